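# Small programmatic fixtures shared across the suite.

# counts matrix -> community_table with one region per `regions` entry
make_table <- function(counts, region = "R1") {
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("t%03d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("s%02d", seq_len(ncol(counts)))
  region <- rep_len(region, ncol(counts))
  community_table(counts, stats::setNames(region, colnames(counts)))
}

# neutral lognormal region: gamma taxa, S samples, multinomial at `depth`
neutral_region <- function(gamma, S, depth, seed, sdlog = 1) {
  withr::with_seed(seed, {
    p <- rlnorm(gamma, 0, sdlog)
    p <- p / sum(p)
    m <- vapply(seq_len(S), function(s) rmultinom(1, depth, p)[, 1L],
                integer(gamma))
  })
  make_table(m)
}

# independent brute-force betaMNTD (double loop over present taxa)
bf_bmntd <- function(x, y, d, weighted = TRUE) {
  sx <- names(x)[x > 0]; sy <- names(y)[y > 0]
  wx <- if (weighted) x[sx] / sum(x[sx]) else rep(1 / length(sx), length(sx))
  wy <- if (weighted) y[sy] / sum(y[sy]) else rep(1 / length(sy), length(sy))
  mx <- vapply(sx, function(a) min(d[a, sy]), numeric(1))
  my <- vapply(sy, function(b) min(d[b, sx]), numeric(1))
  0.5 * (sum(wx * mx) + sum(wy * my))
}

# 3-tip toy distance matrix: d(A,B) = 2, d(A,C) = d(B,C) = 4
toy_dist3 <- function() {
  matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
         dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
}
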