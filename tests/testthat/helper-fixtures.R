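# Small in-code fixtures shared across test files.

# toy cohort: n_sep genes separate the classes cleanly, the rest are noise
toy_cohort <- function(n_pos = 6, n_neg = 6, n_normal = 0, n_sep = 1,
                       n_noise = 10, gap = 6, seed = 42,
                       er = 0, her2 = 3) {
  set.seed(seed)
  n <- n_pos + n_neg + n_normal
  labels <- rep(c("IBC", "nonIBC", "normal"), c(n_pos, n_neg, n_normal))
  ids <- sprintf("T%02d", seq_len(n))
  m <- matrix(rnorm((n_sep + n_noise) * n), n_sep + n_noise, n,
              dimnames = list(sprintf("g%02d", seq_len(n_sep + n_noise)), ids))
  if (n_sep > 0)
    m[seq_len(n_sep), labels == "IBC"] <- m[seq_len(n_sep), labels == "IBC"] + gap
  ann <- data.frame(sample_id = ids, class_label = labels,
                    er_score = er, her2_score = her2,
                    stringsAsFactors = FALSE)
  ExpressionCohort(m, ann)
}

# brute-force Calinski-Harabasz: double loops over clusters, no matrix tricks
ch_bruteforce <- function(x, labels) {
  x <- as.matrix(x)
  n <- nrow(x)
  ks <- unique(labels)
  if (length(ks) < 2 || length(ks) >= n) return(NA_real_)
  grand <- colSums(x) / n
  W <- 0
  B <- 0
  for (cl in ks) {
    rows <- which(labels == cl)
    cent <- colSums(x[rows, , drop = FALSE]) / length(rows)
    for (i in rows) W <- W + sum((x[i, ] - cent)^2)
    B <- B + length(rows) * sum((cent - grand)^2)
  }
  if (W == 0) return(NA_real_)
  (B / (length(ks) - 1)) / (W / (n - length(ks)))
}

# brute-force Mantel-Haenszel log-rank: one 2x2 table per distinct event time
logrank_bruteforce <- function(time, event, group) {
  g <- sort(unique(group))
  stopifnot(length(g) == 2)
  times <- sort(unique(time[event == 1]))
  O <- 0; E <- 0; V <- 0
  for (t in times) {
    at_risk <- time >= t
    n1 <- sum(at_risk & group == g[1])
    n2 <- sum(at_risk & group == g[2])
    d1 <- sum(time == t & event == 1 & group == g[1])
    d2 <- sum(time == t & event == 1 & group == g[2])
    n <- n1 + n2; d <- d1 + d2
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
  }
  chisq <- (O - E)^2 / V
  list(chisq = chisq, observed = O, expected = E)
}

# brute-force Spearman: rank both vectors, then textbook Pearson formula
spearman_bruteforce <- function(a, b) {
  ra <- rank(a); rb <- rank(b)
  ma <- mean(ra); mb <- mean(rb)
  sum((ra - ma) * (rb - mb)) /
    sqrt(sum((ra - ma)^2) * sum((rb - mb)^2))
}

demo_panel_path <- function() {
  system.file("extdata", "synthetic_pam50_panel.tsv", package = "ibcsig")
}
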