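# shared fixtures and independent oracles

# printed per-pair karyotype table (arms in µm) used across tests
table1 <- function() urechis_arms()

# printed per-row values of the published karyotype table
table1_printed <- function() {
  data.frame(
    chr = 1:15,
    rl = c(7.09, 6.75, 10.1, 6.18, 6.50, 7.42, 7.09, 7.79, 6.82, 5.41,
           6.50, 6.36, 6.72, 5.26, 4.01),
    ar = c(1.12, 1.18, 1.42, 1.56, 1.68, 2.08, 2.37, 2.55, 3.35, 4.40,
           6.27, Inf, Inf, Inf, Inf),
    type = c(rep("m", 5), rep("sm", 3), rep("st", 3), rep("t", 4))
  )
}

# printed flow-cytometry table (peak means and derived columns)
table2_printed <- function() {
  cbind(urechis_flow_peaks(),
        ratio = c(0.71, 0.77, 0.71, 0.68, 0.78, 0.68, 0.75, 0.74, 0.85, 0.72),
        pg = c(1.78, 1.92, 1.79, 1.69, 1.95, 1.71, 1.88, 1.85, 2.13, 1.79),
        mb = c(869.70, 937.81, 873.21, 828.15, 954.85, 836.45, 921.06,
               905.41, 1043.60, 875.57))
}

# independent oracle: minimum-cost perfect matching by full enumeration of
# all (n-1)!! matchings (kept free of any package pairing code)
brute_force_matching_cost <- function(d) {
  rec <- function(avail) {
    if (length(avail) == 0L) return(0)
    i <- avail[1L]
    rest <- avail[-1L]
    best <- Inf
    for (k in seq_along(rest)) {
      cost <- d[i, rest[k]] + rec(rest[-k])
      if (cost < best) best <- cost
    }
    best
  }
  rec(seq_len(nrow(d)))
}

# the pairing distance definition, written out independently of the package
pairing_distance <- function(total, ci, w_len = 1, w_cen = 1) {
  w_len * abs(outer(total, total, "-")) / mean(total) +
    w_cen * abs(outer(ci, ci, "-"))
}

# random cell of n_chr chromosomes with plausible morphology
random_cell <- function(n_chr) {
  q <- runif(n_chr, 1.5, 4)
  p <- q * runif(n_chr, 0, 1)
  classify_cell(data.frame(short_arm_um = p, long_arm_um = q))
}

# random true karyotype spanning all four Levan classes, every AR at least
# 5% away from a class boundary
random_true_karyotype <- function(n_pairs) {
  stopifnot(n_pairs >= 4)
  types <- c("m", "sm", "st", "t",
             sample(levan_types, n_pairs - 4, replace = TRUE))
  ar <- vapply(types, function(tp) switch(tp,
    m = runif(1, 1.05, 1.61), sm = runif(1, 1.79, 2.85),
    st = runif(1, 3.15, 6.65), t = Inf), numeric(1))
  total <- runif(n_pairs, 2, 6)
  p <- ifelse(is.infinite(ar), 0, total / (1 + ar))
  data.frame(short_arm_um = p, long_arm_um = total - p,
             levan_type = types, stringsAsFactors = FALSE)
}
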