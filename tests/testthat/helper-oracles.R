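# Independent enumeration oracles used to check the package's statistics
# and tree search. These deliberately share no code with the implementation.

# Exact two-sided binomial p against p0 = 0.5, by summing all outcomes no
# more probable than the observed one (R's tolerance convention).
oracle_binom_p <- function(x, n) {
  probs <- dbinom(0:n, n, 0.5)
  sum(probs[probs <= probs[x + 1] * (1 + 1e-7)])
}

# Fisher exact two-sided p for the 2x2 table rbind(c(a, b), c(c, d)),
# by enumerating all tables with the observed margins.
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + c          # first-column total
  n_ <- b + d         # second-column total
  k <- a + b          # first-row total
  x <- max(0, k - n_):min(k, m)
  probs <- dhyper(x, m, n_, k)
  sum(probs[probs <= dhyper(a, m, n_, k) * (1 + 1e-7)])
}

# Exact two-sided Mann-Whitney p for tie-free samples, by enumerating all
# assignments of the pooled observations to the first group.
oracle_mw_p <- function(x, y) {
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  nx <- length(x)
  u_of <- function(xs, ys) sum(outer(xs, ys, ">"))
  u_obs <- u_of(x, y)
  idx <- utils::combn(length(pooled), nx)
  us <- apply(idx, 2, function(i) u_of(pooled[i], pooled[-i]))
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Minimum parsimony score of a binary mutation x region matrix with a
# germline (all-absent) outgroup, via phangorn Fitch scoring over every
# unrooted topology on the regions plus the germline tip.
oracle_parsimony <- function(mat) {
  tips <- c(colnames(mat), "germline")
  states <- rbind(t(mat), germline = rep(0L, nrow(mat)))
  dat <- phangorn::phyDat(states, type = "USER", levels = c(0L, 1L))
  trees <- phangorn::allTrees(length(tips), rooted = FALSE,
                              tip.label = tips)
  min(vapply(trees, function(tr) phangorn::parsimony(tr, dat), numeric(1)))
}

# Random binary presence matrix with no all-zero rows.
random_presence_matrix <- function(n_mut, n_reg, p = 0.5) {
  mat <- matrix(rbinom(n_mut * n_reg, 1, p), n_mut, n_reg)
  zero <- rowSums(mat) == 0
  mat[cbind(which(zero), sample.int(n_reg, sum(zero), replace = TRUE))] <- 1L
  dimnames(mat) <- list(paste0("m", seq_len(n_mut)),
                        paste0("R", seq_len(n_reg)))
  mat
}
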