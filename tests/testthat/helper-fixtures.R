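# shared test fixtures, built in code

FIXTURE_MD5 <- c("3f8ebf2cf87e73d373fdcc87687eb7fd",   # horry_reanalysis.csv
                 "285fd239f3f441f3517fc28b84aa3197")   # replication.csv

table1 <- function() {
  response_table(
    rbind(fyc = c(71, 26, 61, 7, 38, 102),
          control = c(69, 23, 30, 5, 48, 79)),
    experiment = "reanalysis"
  )
}

table2 <- function() {
  response_table(
    rbind(fyc = c(112, 147, 107, 31, 184, 151),
          control = c(110, 167, 67, 50, 194, 100)),
    experiment = "replication"
  )
}

# expected counts under known parameters, as an (optionally rounded) table
expected_table <- function(spec, params, n_cp, n_ca, round_counts = TRUE) {
  p <- lineup2ht:::tree_probs(params[, "dP"], params[, "dA"],
                              params[, "b"], params[, "g"],
                              spec$design$suspect_constant)
  K <- length(spec$conditions)
  n_cp <- rep_len(n_cp, K)
  n_ca <- rep_len(n_ca, K)
  counts <- cbind(n_cp * p[, 1:3, drop = FALSE], n_ca * p[, 4:6, drop = FALSE])
  if (round_counts) counts <- round(counts)
  response_table(counts, conditions = spec$conditions,
                 check_integer = round_counts)
}

interior_params <- function() {
  m <- rbind(c(0.40, 0.15, 0.10, 0.45),
             c(0.55, 0.15, 0.10, 0.65))
  colnames(m) <- c("dP", "dA", "b", "g")
  rownames(m) <- c("fyc", "control")
  m
}
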