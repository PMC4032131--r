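## Exact branch-expectation Patterson's D for the spatial stepping-stone
## model, by first-step analysis of the structured coalescent.
##
## The sampled chromosomes relevant to D are the Neandertal (N), one African
## (A) and one European (E); the chimpanzee only polarizes alleles and never
## disturbs a qualifying clade.  Before the Neandertal split the (A, E) pair
## wanders the modern-human range (a finite Markov chain over ordered deme
## pairs, with within-deme coalescence as absorption) while N wanders the
## Neandertal range; the two processes cannot interact, so their joint law
## at the split time is the product of two matrix exponentials pushed
## through the colonization-reversal and regime-change epochs.  After the
## split the chain is reconnected and time-homogeneous, so the expected
## ABBA weight (lifetime of a {N,E} clade before it meets A) and BABA
## weight solve sparse linear systems on the three-lineage position space.
## E[D] = (E[ABBA] - E[BABA]) / (E[ABBA] + E[BABA]), free of both the
## mutation rate and Monte Carlo noise.

pair_idx <- function(x, y, K) (x - 1L) * K + y

# migration generator acting on one coordinate of a product chain
lift_generator <- function(M, coord, K) {
  i_idx <- integer(0); j_idx <- integer(0); val <- numeric(0)
  nz <- which(M > 0, arr.ind = TRUE)
  if (nrow(nz) == 0) return(Matrix::sparseMatrix(i = 1, j = 1, x = 0,
                                                 dims = c(K * K, K * K)))
  for (r in seq_len(nrow(nz))) {
    from <- nz[r, 1]; to <- nz[r, 2]; rate <- M[from, to]
    other <- seq_len(K)
    if (coord == 1) {
      s_from <- pair_idx(from, other, K); s_to <- pair_idx(to, other, K)
    } else {
      s_from <- pair_idx(other, from, K); s_to <- pair_idx(other, to, K)
    }
    i_idx <- c(i_idx, s_from); j_idx <- c(j_idx, s_to)
    val <- c(val, rep(rate, K))
  }
  Matrix::sparseMatrix(i = i_idx, j = j_idx, x = val,
                       dims = c(K * K, K * K))
}

#' Exact branch-expectation Patterson's D under the spatial model
#'
#' Computes the expectation of the branch-length Patterson's D for the
#' four-taxon panel (chimp, Neandertal, one African, one European) under
#' the spatial stepping-stone model, with no simulation: the distribution
#' of the three relevant lineages at the Neandertal split time is obtained
#' by matrix exponentials over the model's epochs, and the expected ABBA
#' and BABA branch weights after the split solve linear systems on the
#' reconnected chain (which is time-homogeneous from the split until the
#' chimpanzee divergence).  The horizon is treated as infinite, which is
#' accurate when the chimp split is much older than the chain's
#' coalescence scale (the function warns otherwise).
#'
#' @param params a [spatial_params()] object.
#' @return a list with `d`, `e_abba`, `e_bbaba`-style components: `d`,
#'   `e_abba`, `e_baba` (expected branch weights, generations) and
#'   `p_pair_coalesced` (probability that the African and European
#'   lineages have already coalesced at the split).
#' @export
expected_patterson_d <- function(params) {
  stopifnot(inherits(params, "spatial_params"))
  demog <- build_spatial_model(params)
  comp <- compile_demography(demog)
  ids <- comp$ids
  K <- length(ids)
  ts <- params$t_neandertal_split
  nea_t <- params$neandertal_sampling_time
  stopifnot(nea_t < ts)

  a0 <- match(demog$sample_demes$african, ids)
  e0 <- match(demog$sample_demes$european, ids)
  n0 <- match(demog$sample_demes$neandertal, ids)

  # pair distribution over ordered (A, E) deme pairs; mass lost to
  # within-deme coalescence simply drops out (a coalesced pair can never
  # head a qualifying clade)
  p <- numeric(K * K)
  p[pair_idx(a0, e0, K)] <- 1
  q <- NULL  # Neandertal lineage marginal, NULL until sampled

  checkpoints <- sort(unique(c(comp$breaks[comp$breaks < ts], nea_t, ts)))
  t_now <- 0
  for (t_next in checkpoints) {
    e <- findInterval(t_now, comp$breaks) + 1L
    dt <- t_next - t_now
    if (dt > 0) {
      M <- comp$migs[[e]]
      Qp <- lift_generator(M, 1, K) + lift_generator(M, 2, K)
      coal <- numeric(K * K)
      coal[pair_idx(seq_len(K), seq_len(K), K)] <- 1 / (2 * comp$sizes[, e])
      Qp <- Qp - Matrix::Diagonal(x = Matrix::rowSums(Qp) + coal)
      p <- as.numeric(p %*% Matrix::expm(Qp * dt))
      if (!is.null(q)) {
        Qn <- M
        diag(Qn) <- 0
        diag(Qn) <- -rowSums(Qn)
        q <- as.numeric(q %*% Matrix::expm(Matrix::Matrix(Qn * dt)))
      }
    }
    t_now <- t_next
    if (t_next == nea_t) {
      q <- numeric(K)
      q[n0] <- 1
    }
    bi <- match(t_next, comp$breaks)
    if (!is.na(bi) && t_next < ts) {
      act <- comp$actions[[bi]]
      if (any(act$frac < 1)) {
        stop("probabilistic lineage moves before the split are not ",
             "supported by the exact computation")
      }
      relabel <- seq_len(K)
      for (a in seq_along(act$from)) {
        relabel[relabel == act$from[a] + 1L] <- act$to[a] + 1L
      }
      if (any(relabel != seq_len(K))) {
        newp <- numeric(K * K)
        grid <- expand.grid(x = seq_len(K), y = seq_len(K))
        src <- pair_idx(grid$x, grid$y, K)
        dst <- pair_idx(relabel[grid$x], relabel[grid$y], K)
        for (s in seq_along(src)) newp[dst[s]] <- newp[dst[s]] + p[src[s]]
        p <- newp
        if (!is.null(q)) {
          newq <- numeric(K)
          for (x in seq_len(K)) newq[relabel[x]] <- newq[relabel[x]] + q[x]
          q <- newq
        }
      }
    }
  }

  # post-split phase: restrict to the reconnected chain
  e_post <- findInterval(ts, comp$breaks) + 1L
  M_post <- comp$migs[[e_post]]
  sizes_post <- comp$sizes[, e_post]
  # pair_idx(x, y) = (x-1)K + y varies over y fastest, so rows are A
  pm <- matrix(p, K, K, byrow = TRUE)
  chain <- sort(unique(c(which(rowSums(pm) + colSums(pm) > 1e-14),
                         which(q > 1e-14),
                         which(M_post > 0, arr.ind = TRUE))))
  k <- length(chain)
  Mc <- M_post[chain, chain, drop = FALSE]
  Nc <- sizes_post[chain]
  gap <- demog$outgroup_split_time - ts
  if (gap < 5 * 2 * sum(Nc)) {
    warning("chimp divergence is close to the chain's coalescence scale; ",
            "the infinite-horizon approximation may be inaccurate")
  }

  # u(x, y): expected coalescence time of two lineages at chain demes x, y
  ku <- k * k
  uidx <- function(x, y) (x - 1L) * k + y
  lift_chain <- function(M, coord) {
    i_idx <- integer(0); j_idx <- integer(0); val <- numeric(0)
    nz <- which(M > 0, arr.ind = TRUE)
    for (r in seq_len(nrow(nz))) {
      from <- nz[r, 1]; to <- nz[r, 2]; rate <- M[from, to]
      other <- seq_len(k)
      if (coord == 1) {
        s_from <- uidx(from, other); s_to <- uidx(to, other)
      } else {
        s_from <- uidx(other, from); s_to <- uidx(other, to)
      }
      i_idx <- c(i_idx, s_from); j_idx <- c(j_idx, s_to)
      val <- c(val, rep(rate, k))
    }
    Matrix::sparseMatrix(i = i_idx, j = j_idx, x = val, dims = c(ku, ku))
  }
  Qu <- lift_chain(Mc, 1) + lift_chain(Mc, 2)
  coal_u <- numeric(ku)
  coal_u[uidx(seq_len(k), seq_len(k))] <- 1 / (2 * Nc)
  Au <- Qu - Matrix::Diagonal(x = Matrix::rowSums(Qu) + coal_u)
  u <- as.numeric(Matrix::solve(Au, rep(-1, ku)))

  # three-lineage system over (N, A, E) chain positions
  k3 <- k^3
  tidx <- function(n, a, e) ((n - 1L) * k + (a - 1L)) * k + e
  lift3 <- function(M, coord) {
    i_idx <- integer(0); j_idx <- integer(0); val <- numeric(0)
    nz <- which(M > 0, arr.ind = TRUE)
    others <- expand.grid(o1 = seq_len(k), o2 = seq_len(k))
    for (r in seq_len(nrow(nz))) {
      from <- nz[r, 1]; to <- nz[r, 2]; rate <- M[from, to]
      if (coord == 1) {
        s_from <- tidx(from, others$o1, others$o2)
        s_to <- tidx(to, others$o1, others$o2)
      } else if (coord == 2) {
        s_from <- tidx(others$o1, from, others$o2)
        s_to <- tidx(others$o1, to, others$o2)
      } else {
        s_from <- tidx(others$o1, others$o2, from)
        s_to <- tidx(others$o1, others$o2, to)
      }
      i_idx <- c(i_idx, s_from); j_idx <- c(j_idx, s_to)
      val <- c(val, rep(rate, nrow(others)))
    }
    Matrix::sparseMatrix(i = i_idx, j = j_idx, x = val, dims = c(k3, k3))
  }
  Q3 <- lift3(Mc, 1) + lift3(Mc, 2) + lift3(Mc, 3)
  grid3 <- expand.grid(n = seq_len(k), a = seq_len(k), e = seq_len(k))
  s3 <- tidx(grid3$n, grid3$a, grid3$e)
  rate_ne <- ifelse(grid3$n == grid3$e, 1 / (2 * Nc[grid3$n]), 0)
  rate_na <- ifelse(grid3$n == grid3$a, 1 / (2 * Nc[grid3$n]), 0)
  rate_ae <- ifelse(grid3$a == grid3$e, 1 / (2 * Nc[grid3$a]), 0)
  coal3 <- numeric(k3)
  coal3[s3] <- rate_ne + rate_na + rate_ae
  A3 <- Q3 - Matrix::Diagonal(x = Matrix::rowSums(Q3) + coal3)
  b_ab <- numeric(k3)
  b_ab[s3] <- rate_ne * u[uidx(grid3$n, grid3$a)]
  b_ba <- numeric(k3)
  b_ba[s3] <- rate_na * u[uidx(grid3$n, grid3$e)]
  v_ab <- as.numeric(Matrix::solve(A3, -b_ab))
  v_ba <- as.numeric(Matrix::solve(A3, -b_ba))

  # combine: independent N and (A, E) laws at the split
  pc <- pm[chain, chain, drop = FALSE]
  qc <- q[chain]
  e_abba <- 0; e_baba <- 0
  for (n in seq_len(k)) {
    if (qc[n] <= 0) next
    for (a in seq_len(k)) {
      pa <- pc[a, ]
      if (all(pa <= 0)) next
      idx <- tidx(n, a, seq_len(k))
      e_abba <- e_abba + qc[n] * sum(pa * v_ab[idx])
      e_baba <- e_baba + qc[n] * sum(pa * v_ba[idx])
    }
  }
  list(d = (e_abba - e_baba) / (e_abba + e_baba),
       e_abba = e_abba, e_baba = e_baba,
       p_pair_coalesced = 1 - sum(pm))
}
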