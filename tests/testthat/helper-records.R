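# Construct a minimal symptom-free record and override selected fields.
make_record <- function(..., patient_id = "t1", timepoint = "baseline") {
  rec <- edclassify:::empty_record(patient_id, timepoint)
  over <- list(...)
  for (nm in names(over)) {
    stopifnot(nm %in% names(rec))
    rec[[nm]] <- over[[nm]]
  }
  rec
}

# Full factorial grid over the 14 interview flags at fixed BMI levels, all
# questionnaire counts zero: the domain of the brute-force rule oracle.
flag_grid <- function(bmis = c(16, 20, 31)) {
  flags <- edclassify:::interview_items()
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), length(flags)))
  names(grid) <- flags
  grid <- grid[rep(seq_len(nrow(grid)), times = length(bmis)), ]
  grid$bmi <- rep(bmis, each = 2^length(flags))
  n <- nrow(grid)
  base <- edclassify:::empty_record(sprintf("G%06d", seq_len(n)), "baseline")
  base[names(grid)] <- grid
  rownames(base) <- NULL
  base
}
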