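## Codon-model machinery: GY94-style Markov model over the 61 sense codons
## with transition/transversion ratio kappa and selection parameter omega,
## uniform codon frequencies.  With uniform frequencies the rate matrix is
## symmetric, so transition probabilities come from a symmetric eigen
## decomposition (fast and numerically stable).

.codon_env <- new.env(parent = emptyenv())

codon_tables <- function() {
  if (!is.null(.codon_env$tab)) return(.codon_env$tab)
  nt <- c("T", "C", "A", "G")
  codons <- as.vector(outer(outer(nt, nt, paste0), nt,
                            function(ab, c) paste0(ab, c)))
  codons <- sort(codons)
  gc <- Biostrings::GENETIC_CODE
  aa <- unname(gc[codons])
  sense <- codons[aa != "*"]
  aa_sense <- aa[aa != "*"]
  n <- length(sense)                      # 61
  stopifnot(n == 61L)

  is_transition <- function(x, y) {
    (x %in% c("A", "G") && y %in% c("A", "G")) ||
      (x %in% c("C", "T") && y %in% c("C", "T"))
  }
  ## sparse description of single-nucleotide neighbours
  from <- integer(0); to <- integer(0)
  ts <- logical(0); syn <- logical(0)
  sp <- strsplit(sense, "")
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      d <- which(sp[[i]] != sp[[j]])
      if (length(d) != 1L) next
      from <- c(from, i); to <- c(to, j)
      ts <- c(ts, is_transition(sp[[i]][d], sp[[j]][d]))
      syn <- c(syn, aa_sense[i] == aa_sense[j])
    }
  }
  .codon_env$tab <- list(codons = sense, aa = aa_sense, n = n,
                         nbr = data.frame(from = from, to = to,
                                          transition = ts, synonymous = syn))
  .codon_env$tab
}

#' GY94-style codon rate matrix with uniform codon frequencies
#'
#' Off-diagonal rates are nonzero only between codons differing at a single
#' nucleotide: `kappa` for synonymous transitions, 1 for synonymous
#' transversions, multiplied by `omega` for nonsynonymous changes.  The
#' matrix is scaled so that the expected number of substitutions per codon
#' per unit time is 1.
#'
#' @param kappa transition/transversion rate ratio.
#' @param omega nonsynonymous/synonymous rate ratio.
#' @return list with `Q` (61 x 61), and the flux fractions `fN`, `fS`
#'   (nonsynonymous/synonymous share of total substitution rate).
#' @export
gy94_rate_matrix <- function(kappa, omega) {
  tab <- codon_tables()
  n <- tab$n
  Q <- matrix(0, n, n)
  r <- ifelse(tab$nbr$transition, kappa, 1) *
    ifelse(tab$nbr$synonymous, 1, omega)
  Q[cbind(tab$nbr$from, tab$nbr$to)] <- r
  pi0 <- 1 / n
  flux <- sum(Q) * pi0
  Q <- Q / flux
  fN <- sum(Q[cbind(tab$nbr$from, tab$nbr$to)[!tab$nbr$synonymous, ,
                                              drop = FALSE]]) * pi0
  diag(Q) <- -rowSums(Q)
  list(Q = Q, fN = fN, fS = 1 - fN)
}

## proportion of mutational opportunity that is nonsynonymous, under
## omega = 1 (the "sites" normalisation)
gy94_site_proportion <- function(kappa) {
  gy94_rate_matrix(kappa, 1)$fN
}

gy94_transition_probs <- function(Q, t) {
  e <- eigen(Q, symmetric = TRUE)
  P <- e$vectors %*% (t(e$vectors) * exp(e$values * t))
  P[P < 1e-300] <- 1e-300
  P
}

#' Log-likelihood of a pairwise codon count matrix under GY94
#'
#' The data are summarised as a 61 x 61 matrix of codon-pair counts over
#' gap-free alignment columns.  The pairwise likelihood treats one sequence
#' as drawn from the stationary (uniform) distribution and the other as its
#' descendant after divergence `t` (substitutions per codon along the whole
#' path); by reversibility this is equivalent to any placement of the root.
#'
#' @param counts 61 x 61 integer matrix, rows = codon in sequence a,
#'   columns = codon in sequence b, indexed as in `codon_tables()$codons`.
#' @param t divergence in expected substitutions per codon.
#' @param kappa transition/transversion ratio.
#' @param omega nonsynonymous/synonymous ratio.
#' @export
gy94_lnL <- function(counts, t, kappa, omega) {
  rm_ <- gy94_rate_matrix(kappa, omega)
  P <- gy94_transition_probs(rm_$Q, t)
  sum(counts * (log(P) - log(61)))
}

#' Maximum-likelihood Ka/Ks estimation under the GY94 codon model
#'
#' Optimises divergence `t`, `kappa` and (unless fixed) `omega` by a fixed
#' coarse grid followed by bounded quasi-Newton refinement, so the result
#' is deterministic for given inputs.  `Ka` and `Ks` are derived from the
#' fitted flux and the omega = 1 site normalisation, so that
#' `Ka/Ks = omega_hat` exactly.
#'
#' @param aln a [codon_alignment].
#' @param fix_omega `NULL` for a free omega, or a fixed value (e.g. 0.5 or
#'   1.0 for the null models of the constraint and neutrality tests).
#' @return list with `lnL`, `t_hat`, `kappa_hat`, `omega_hat`, `ka`, `ks`.
#' @export
ml_kaks <- function(aln, fix_omega = NULL) {
  counts <- codon_pair_counts(aln)
  fit_gy94_counts(counts, fix_omega)
}

fit_gy94_counts <- function(counts, fix_omega = NULL) {
  stopifnot(all(dim(counts) == 61L), sum(counts) > 0)
  free_omega <- is.null(fix_omega)
  nz <- which(counts > 0)
  cnz <- counts[nz]
  ntot <- sum(cnz)

  ## profile likelihood over t for fixed (kappa, omega): one eigen
  ## decomposition, then a cheap 1-D golden-section search on log t.
  ## Only the transition probabilities of observed codon pairs are needed:
  ## P_ij(t) = sum_k V_ik V_jk exp(lambda_k t), assembled as one
  ## m x 61 product over the m distinct observed pairs.
  ij <- arrayInd(nz, c(61L, 61L))
  profile_t <- function(kappa, omega) {
    e <- eigen(gy94_rate_matrix(kappa, omega)$Q, symmetric = TRUE)
    W <- e$vectors[ij[, 1], , drop = FALSE] *
      e$vectors[ij[, 2], , drop = FALSE]
    lam <- e$values
    f <- function(logt) {
      p <- W %*% exp(lam * exp(logt))
      p[p < 1e-300] <- 1e-300
      -(sum(cnz * log(p)) - ntot * log(61))
    }
    op <- stats::optimize(f, interval = log(c(1e-6, 50)), tol = 1e-6)
    list(t = exp(op$minimum), lnL = -op$objective)
  }

  if (free_omega) {
    obj <- function(par) -profile_t(exp(par[1]), exp(par[2]))$lnL
    grid <- expand.grid(k = log(c(1, 2, 5)),
                        o = log(c(0.02, 0.1, 0.3, 0.7, 1.5, 4)))
    vals <- apply(grid, 1L, obj)
    g0 <- as.numeric(grid[which.min(vals), ])
    fit <- stats::optim(g0, obj, method = "L-BFGS-B",
                        lower = log(c(0.01, 1e-4)), upper = log(c(20, 10)),
                        control = list(factr = 1e10, maxit = 100))
    kappa_hat <- exp(fit$par[1]); omega_hat <- exp(fit$par[2])
    pr <- profile_t(kappa_hat, omega_hat)
  } else {
    obj <- function(logk) -profile_t(exp(logk), fix_omega)$lnL
    op <- stats::optimize(obj, interval = log(c(0.01, 20)), tol = 1e-5)
    kappa_hat <- exp(op$minimum); omega_hat <- fix_omega
    pr <- profile_t(kappa_hat, omega_hat)
  }
  t_hat <- pr$t
  lnL <- pr$lnL
  if (!is.finite(lnL)) stop("non-finite codon-model likelihood")
  rm_ <- gy94_rate_matrix(kappa_hat, omega_hat)
  rhoN <- gy94_site_proportion(kappa_hat)
  ka <- t_hat * rm_$fN / (3 * rhoN)
  ks <- t_hat * rm_$fS / (3 * (1 - rhoN))
  list(lnL = lnL, t_hat = t_hat, kappa_hat = kappa_hat,
       omega_hat = omega_hat, ka = ka, ks = ks)
}

#' Simulate a pair of diverged codon sequences under GY94
#'
#' One sequence is drawn from the uniform stationary distribution; the
#' other is its descendant after `t` expected substitutions per codon.
#'
#' @param n_codons number of codons.
#' @param t divergence (substitutions per codon on the whole path).
#' @param kappa transition/transversion ratio.
#' @param omega nonsynonymous/synonymous ratio.
#' @param as_counts if `TRUE` return the 61 x 61 pair-count matrix,
#'   otherwise a list of two codon-string vectors.
#' @export
simulate_codon_pair <- function(n_codons, t, kappa, omega,
                                as_counts = FALSE) {
  tab <- codon_tables()
  rm_ <- gy94_rate_matrix(kappa, omega)
  P <- gy94_transition_probs(rm_$Q, t)
  P <- P / rowSums(P)
  a <- sample.int(61L, n_codons, replace = TRUE)
  b <- vapply(a, function(i) sample.int(61L, 1L, prob = P[i, ]), 0L)
  if (as_counts) {
    m <- matrix(0L, 61L, 61L)
    for (i in seq_len(n_codons)) m[a[i], b[i]] <- m[a[i], b[i]] + 1L
    m
  } else {
    list(a = tab$codons[a], b = tab$codons[b])
  }
}

codon_pair_counts <- function(aln) {
  tab <- codon_tables()
  ia <- match(aln$a, tab$codons)
  ib <- match(aln$b, tab$codons)
  keep <- !is.na(ia) & !is.na(ib)
  m <- matrix(0L, 61L, 61L)
  for (i in which(keep)) m[ia[i], ib[i]] <- m[ia[i], ib[i]] + 1L
  m
}
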