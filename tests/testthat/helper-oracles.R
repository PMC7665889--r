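# Independent oracles used to verify the package's engines. These are
# deliberately naive implementations (exhaustive search, dense grids,
# textbook likelihoods) that share no code with the functions they check.

# Exhaustive recursive segmentation with cost-complexity pruning (CART):
# grow the full binary tree (best-SSE split per node, exhaustive over split
# points, minsplit/minbucket constraints, leftmost tie-break), then apply
# weakest-link pruning at alpha = cp * SSE(root): repeatedly collapse the
# internal node whose per-split SSE gain g(t) = (SSE(t) - sum SSE(leaves)) /
# (n_leaves - 1) is smallest, while that gain is below alpha.
oracle_segment <- function(y, minsplit = 4, cp = 0.05,
                           minbucket = round(minsplit / 3)) {
  sse <- function(v) sum((v - mean(v))^2)
  root_sse <- sse(y)
  grow <- function(lo, hi) {
    n <- hi - lo + 1; v <- y[lo:hi]
    node <- list(lo = lo, hi = hi, ss = sse(v), leaf = TRUE)
    if (n < minsplit || node$ss <= 0) return(node)
    best_imp <- -Inf; best_k <- NA
    for (k in seq_len(n - 1)) {
      if (k < minbucket || (n - k) < minbucket) next
      imp <- node$ss - sse(v[1:k]) - sse(v[(k + 1):n])
      if (imp > best_imp + 1e-12) { best_imp <- imp; best_k <- k }
    }
    if (is.na(best_k) || best_imp <= 0) return(node)
    node$leaf <- FALSE
    node$left <- grow(lo, lo + best_k - 1)
    node$right <- grow(lo + best_k, hi)
    node
  }
  tree <- grow(1, length(y))
  leaves_ss <- function(nd) if (nd$leaf) nd$ss else
    leaves_ss(nd$left) + leaves_ss(nd$right)
  n_leaves <- function(nd) if (nd$leaf) 1L else
    n_leaves(nd$left) + n_leaves(nd$right)
  internal_gs <- function(nd, path = character()) {
    if (nd$leaf) return(list())
    g <- (nd$ss - leaves_ss(nd)) / (n_leaves(nd) - 1L)
    c(list(list(g = g, path = path)),
      internal_gs(nd$left, c(path, "left")),
      internal_gs(nd$right, c(path, "right")))
  }
  prune_at <- function(nd, path) {
    if (!length(path)) return(list(lo = nd$lo, hi = nd$hi, ss = nd$ss, leaf = TRUE))
    if (path[1] == "left") nd$left <- prune_at(nd$left, path[-1])
    else nd$right <- prune_at(nd$right, path[-1])
    nd
  }
  repeat {
    gs <- internal_gs(tree)
    if (!length(gs)) break
    gvals <- vapply(gs, `[[`, 0, "g")
    if (min(gvals) >= cp * root_sse - 1e-12) break
    tree <- prune_at(tree, gs[[which.min(gvals)]]$path)
  }
  bounds <- integer()
  walk <- function(nd) {
    if (nd$leaf) { if (nd$lo > 1) bounds <<- c(bounds, nd$lo); return() }
    walk(nd$left); walk(nd$right)
  }
  walk(tree)
  sort(bounds)
}

# segment first-indices (1-based, excluding 1) from a fitted segment_model,
# for a single-chromosome track whose bins are 0..n-1
model_boundaries <- function(model, chrom = "chr1") {
  s <- model$segments[model$segments$chrom == chrom, ]
  sort(s$first_bin[s$first_bin > 0] + 1L)
}

# dense 2-D grid maximization of the fixed-dispersion beta-binomial
# likelihood with logit mean = intercept (+ effect for group 2)
oracle_betabin_grid <- function(y, n, group, phi, lim = 8, step = 0.01) {
  dbb <- function(y, n, pi) {
    if (phi <= 0) return(sum(dbinom(y, n, pi, log = TRUE)))
    a <- pi * (1 - phi) / phi
    b <- (1 - pi) * (1 - phi) / phi
    sum(lchoose(n, y) + lbeta(y + a, n - y + b) - lbeta(a, b))
  }
  etas <- seq(-lim, lim, by = step)
  g2 <- group == unique(group)[2]
  ll_null <- max(vapply(etas, function(e) dbb(y, n, plogis(e)), 0))
  # the two group likelihoods share no parameters, so maximize separately
  ll_full <- max(vapply(etas, function(e) dbb(y[!g2], n[!g2], plogis(e)), 0)) +
    max(vapply(etas, function(e) dbb(y[g2], n[g2], plogis(e)), 0))
  list(ll_null = ll_null, ll_full = ll_full,
       stat = 2 * (ll_full - ll_null))
}

# binomial logistic-regression LRT of group on allelic proportions
oracle_binom_lrt <- function(m, p, group) {
  g <- factor(group)
  full <- glm(cbind(m, p) ~ g, family = binomial())
  null <- glm(cbind(m, p) ~ 1, family = binomial())
  stat <- null$deviance - full$deviance
  list(stat = stat, df = null$df.residual - full$df.residual,
       p = pchisq(stat, null$df.residual - full$df.residual,
                  lower.tail = FALSE))
}

# NB log-likelihood of counts at given means and dispersion
nb_loglik <- function(y, mu, dispersion) {
  if (dispersion <= 0) return(sum(dpois(y, mu, log = TRUE)))
  sum(dnbinom(y, mu = mu, size = 1 / dispersion, log = TRUE))
}
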