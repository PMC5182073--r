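# Shared fixture builders and independent oracles for the test suite.

# Write extended-GMT lines to a temp file and return the path.
write_gmtx_lines <- function(lines) {
  f <- tempfile(fileext = ".gmtx")
  writeLines(lines, f)
  f
}

# Tiny probe matrix built by hand: `reps` is a list (one entry per probe) of
# replicate-by-sample matrices.
tiny_probe_matrix <- function(reps, probe_gene, sample_class) {
  n_rep <- nrow(reps[[1]])
  samples <- names(sample_class)
  ints <- array(0, dim = c(length(reps), n_rep, length(samples)),
                dimnames = list(names(reps), NULL, samples))
  for (i in seq_along(reps)) ints[i, , ] <- reps[[i]]
  probe_matrix(ints, probe_gene, sample_class)
}

# Independent pair-counting AUC oracle (Mann-Whitney definition, ties half).
auc_pairs <- function(case, control) {
  wins <- 0
  for (x in case) for (y in control)
    wins <- wins + (x > y) + 0.5 * (x == y)
  wins / (length(case) * length(control))
}

# Independent term-by-term PAS oracle: explicit loop over genes.
pas_oracle <- function(arr, cnr_vec) {
  s <- 0
  for (g in names(arr)) s <- s + arr[[g]] * log10(cnr_vec[[g]])
  c(raw = s, pas2 = s / length(arr))
}

# Stack-based partner matching: returns the content of the final trailing
# parenthetical, or NA if absent/unbalanced. Independent of the package's
# reverse-scan implementation.
branch_oracle <- function(x) {
  chars <- strsplit(x, "")[[1]]
  n <- length(chars)
  if (chars[n] != ")") return(NA_character_)
  stack <- integer(0)
  partner <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    if (chars[i] == "(") stack <- c(stack, i)
    else if (chars[i] == ")") {
      if (!length(stack)) return(NA_character_)
      partner[i] <- stack[length(stack)]
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack)) return(NA_character_)
  substr(x, partner[n] + 1L, n - 1L)
}

# End-to-end run of one simulated study: returns the selected pathway-level
# marker table for case vs control.
run_pathway_markers <- function(study, case = "AML", control = "Normal",
                                fraction = 0.10) {
  res <- suppressMessages(suppressWarnings(
    run_pipeline(pipeline_config(tempfile("pasrun"), study = study,
                                 control_class = control,
                                 fraction = fraction))))
  res$markers[[paste0(case, "_vs_", control, ".pathway")]]
}
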