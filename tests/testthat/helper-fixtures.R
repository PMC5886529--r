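# Shared fixtures: small designs and canonical parameter points used across
# test files. Everything is generated in code; no stored data.

task_ratios <- c(0.1, 0.25, 0.5, 0.75, 0.9)

small_design <- function(n = 40, ratios = task_ratios) {
  sim_design(ratios = ratios, trials_per_ratio = n)
}

# parameterization that produces plentiful changes of mind (large Weber
# fraction, memory-free sampling, fast-saturating certainty, longer flights)
com_rich_params <- function() {
  model_params(omega = 0.39, D = 1, W = 2)
}

com_rich_design <- function(n, ratios = c(0.5, 0.75, 0.9)) {
  sim_design(ratios = ratios, trials_per_ratio = n,
             tf_mean_s = 0.8, tf_sd_s = 0.15)
}

# per-trial change-of-mind summaries of a simulated block, restricted to
# trials with a defined lift-off window; $idx maps back into ds$meta
block_coms <- function(ds) {
  idx <- which(rowSums(is.na(ds$norm)) == 0)
  res <- lapply(idx, function(i) {
    detect_changes_of_mind(ds$norm[i, ], correct = ds$meta$correct[i])
  })
  list(idx = idx,
       counts = vapply(res, `[[`, integer(1), "count"),
       directions = unlist(lapply(res, `[[`, "directions")))
}
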