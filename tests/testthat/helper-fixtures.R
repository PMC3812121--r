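# Minimal hand-built haplotype panel around a 0/1 chromosome-by-site matrix.
make_panel <- function(geno, pos = NULL) {
  if (is.null(colnames(geno)))
    colnames(geno) <- sprintf("s%02d", seq_len(ncol(geno)))
  if (is.null(rownames(geno)))
    rownames(geno) <- sprintf("chr%03d", seq_len(nrow(geno)))
  if (is.null(pos)) pos <- seq_len(ncol(geno)) * 10L
  structure(
    list(genotypes = geno,
         sites = data.frame(id = colnames(geno), pos = pos,
                            ancestral = "0"),
         truth = NULL, risk_hap = NA_character_, protective_hap = NA_character_,
         config = list(region_length = max(pos) + 10L)),
    class = "haplotype_panel")
}

# Independent LD oracle: expand gamete counts to explicit vectors and use
# elementary moments (no shared code with ld_stats()).
ld_oracle <- function(n_AB, n_Ab, n_aB, n_ab) {
  x <- rep(c(1, 1, 0, 0), c(n_AB, n_Ab, n_aB, n_ab))
  y <- rep(c(1, 0, 1, 0), c(n_AB, n_Ab, n_aB, n_ab))
  D <- mean(x * y) - mean(x) * mean(y)
  pA <- mean(x); pB <- mean(y)
  Dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB)
          else        min(pA * pB, (1 - pA) * (1 - pB))
  list(D = D,
       D_prime = if (D == 0) 0 else abs(D) / Dmax,
       r2 = suppressWarnings(stats::cor(x, y))^2)
}

# Independent one-tail hypergeometric oracle by direct choose() summation.
fisher_tail_oracle <- function(a, n1, c, n2, tail) {
  K <- a + c; N <- n1 + n2
  support <- max(0, K - n2):min(K, n1)
  pmf <- choose(K, support) * choose(N - K, n1 - support) / choose(N, n1)
  if (tail == "depletion") sum(pmf[support <= a]) else sum(pmf[support >= a])
}

# Iteratively-refined grid search over the binomial log-likelihood of
# y ~ b0 + b1*d1 + b2*d2; independent of glm().
glm_grid_oracle <- function(y, d1, d2, span = 8, rounds = 20, pts = 13) {
  loglik <- function(b0, b1, b2) {
    eta <- b0 + b1 * d1 + b2 * d2
    sum(y * eta - log1p(exp(eta)))
  }
  centre <- c(0, 0, 0)
  for (r in seq_len(rounds)) {
    g <- lapply(centre, function(m) seq(m - span, m + span, length.out = pts))
    grid <- expand.grid(b0 = g[[1]], b1 = g[[2]], b2 = g[[3]])
    ll <- mapply(loglik, grid$b0, grid$b1, grid$b2)
    centre <- as.numeric(grid[which.max(ll), ])
    span <- span * 2 / (pts - 1)   # keep the previous neighbourhood covered
  }
  centre
}
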