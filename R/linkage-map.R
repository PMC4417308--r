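# Linkage-group formation, marker ordering and map construction.

#' Partition markers into linkage groups
#'
#' Single-linkage transitive closure over the pairwise linkage graph: two
#' markers are connected when their LOD exceeds `lod_min` and their
#' recombination fraction is below `rf_max`. Groups are named by their
#' smallest member id. Groups below `min_size` are reported unplaced rather
#' than forced into the map.
#'
#' @param tp All-pairs table from [two_point_table()].
#' @param lod_min Grouping LOD threshold (default 3).
#' @param rf_max Maximum recombination fraction for an edge (default 0.5).
#' @param min_size Smallest group placed on the map (default 2).
#' @return List: `groups` (named list of marker-id vectors, ordered by
#'   smallest member id) and `unplaced` (marker ids in undersized groups).
#' @export
group_markers <- function(tp, lod_min = 3, rf_max = 0.5, min_size = 2) {
  ids <- tp$ids
  edge <- which(tp$lod > lod_min & tp$rf < rf_max & upper.tri(tp$lod),
                arr.ind = TRUE)
  g <- igraph::graph_from_data_frame(
    data.frame(from = ids[edge[, 1]], to = ids[edge[, 2]]),
    directed = FALSE, vertices = data.frame(name = ids))
  comp <- igraph::components(g)
  membership <- comp$membership[ids]
  groups <- split(ids, membership)
  names(groups) <- vapply(groups, function(x) min(x), character(1))
  groups <- groups[order(names(groups))]
  small <- lengths(groups) < min_size
  list(groups = groups[!small],
       unplaced = unlist(groups[small], use.names = FALSE))
}

# internal: coherence diagnostics for a tentative merge of groups A and B.
# Distances are routed through informative pairs (shortest path). Among
# cross pairs predicted closer than `pred_max` cM:
#   * `contradiction`: fraction whose observed LOD is below `lod_lo`. A
#     genuine within-chromosome gap leaves the facing markers both
#     predicted close and observably linked; a spurious bridge predicts
#     closeness the data contradict.
#   * `support_mat` / `support_pat`: fraction with LOD > 1 among the
#     cross pairs informative in only that parent. A real gap is crossed
#     by recombination in both parents' meioses; a spurious bridge is a
#     fluctuation of one parent's transmission pattern, so the other
#     parent's pairs stay null.
.merge_diagnostics <- function(tp, A, B, pred_max = 35, lod_lo = 0.7) {
  out <- list(contradiction = NA_real_, support_mat = NA_real_,
              support_pat = NA_real_)
  ids <- c(A, B)
  rf <- tp$rf[ids, ids]
  nim <- tp$n_informative[ids, ids]
  lod <- tp$lod[ids, ids]
  d <- kosambi(pmin(rf, 0.499))
  inf <- nim > 0 & rf < 0.45
  edge <- which(inf & upper.tri(inf), arr.ind = TRUE)
  if (nrow(edge) == 0) return(out)
  g <- igraph::graph_from_data_frame(
    data.frame(from = ids[edge[, 1]], to = ids[edge[, 2]],
               weight = d[edge]),
    directed = FALSE, vertices = data.frame(name = ids))
  sp <- igraph::distances(g)[ids, ids]
  inA <- ids %in% A
  cross <- outer(inA, !inA, "&") | outer(!inA, inA, "&")
  sel <- cross & upper.tri(sp) & sp < pred_max & nim > 0
  if (!sum(sel)) return(out)
  out$contradiction <- mean(lod[sel] < lod_lo)
  mat_only <- tp$phase_mat[ids, ids] != "n/a" & tp$phase_pat[ids, ids] == "n/a"
  pat_only <- tp$phase_pat[ids, ids] != "n/a" & tp$phase_mat[ids, ids] == "n/a"
  if (sum(sel & mat_only) >= 2)
    out$support_mat <- mean(lod[sel & mat_only] > 1)
  if (sum(sel & pat_only) >= 2)
    out$support_pat <- mean(lod[sel & pat_only] > 1)
  out
}

#' Linkage grouping robust to sparse regions and spurious linkage
#'
#' At a few hundred markers the grouping test runs over ~10^5 marker pairs,
#' so a handful of spurious LOD > `lod_min` edges is expected by chance and,
#' under single-linkage closure, a single such edge fuses two chromosomes;
#' conversely a long marker-sparse region can split one chromosome at a
#' strict threshold. This routine therefore (1) forms groups at a
#' family-wise-adjusted threshold (`max(lod_min, grouping_lod(n, fwer))`),
#' then (2) considers every group pair still connected by an edge above
#' `lod_min` and merges it only when the linkage geometry is coherent: the
#' cross pairs predicted close by distance routing must actually look
#' linked (contradiction fraction below `max_contradiction`). Merges are
#' applied best-first and re-evaluated after each acceptance.
#'
#' A merge additionally requires support in both parents' meioses
#' (`min_support`): cross linkage visible only in one parent's informative
#' pairs is the signature of a transmission-pattern fluctuation, not of a
#' physical gap.
#'
#' @inheritParams group_markers
#' @param fwer Family-wise expected false-edge count for the strict stage
#'   (default 0.001).
#' @param max_contradiction Maximum tolerated contradiction fraction for a
#'   merge (default 0.3).
#' @param min_support Minimum per-parent supported fraction among
#'   predicted-close cross pairs (default 0.3); both parental channels must
#'   qualify.
#' @return As [group_markers()].
#' @export
group_markers_robust <- function(tp, lod_min = 3, rf_max = 0.5,
                                 min_size = 2, fwer = 0.001,
                                 max_contradiction = 0.3,
                                 min_support = 0.3) {
  lod_hi <- max(lod_min, grouping_lod(length(tp$ids), fwer))
  grp <- group_markers(tp, lod_hi, rf_max, min_size = 1)
  groups <- grp$groups
  repeat {
    if (length(groups) < 2) break
    memb <- rep(names(groups), lengths(groups))
    names(memb) <- unlist(groups)
    m <- memb[tp$ids]
    e <- which(tp$lod > lod_min & tp$rf < rf_max & upper.tri(tp$lod),
               arr.ind = TRUE)
    gi <- m[e[, 1]]; gj <- m[e[, 2]]
    cross <- gi != gj
    if (!any(cross)) break
    key <- unique(paste(pmin(gi[cross], gj[cross]),
                        pmax(gi[cross], gj[cross])))
    cand <- do.call(rbind, strsplit(key, " "))
    diag <- lapply(seq_len(nrow(cand)), function(k) {
      .merge_diagnostics(tp, groups[[cand[k, 1]]], groups[[cand[k, 2]]])
    })
    fc <- vapply(diag, `[[`, numeric(1), "contradiction")
    sm <- vapply(diag, `[[`, numeric(1), "support_mat")
    sp <- vapply(diag, `[[`, numeric(1), "support_pat")
    ok <- which(!is.na(fc) & fc < max_contradiction &
                  !is.na(sm) & sm >= min_support &
                  !is.na(sp) & sp >= min_support)
    if (!length(ok)) break
    best <- ok[which.min(fc[ok])]
    a <- cand[best, 1]; b <- cand[best, 2]
    merged <- sort(c(groups[[a]], groups[[b]]))
    groups[[a]] <- NULL; groups[[b]] <- NULL
    groups[[min(merged)]] <- merged
    groups <- groups[order(names(groups))]
  }
  small <- lengths(groups) < min_size
  list(groups = groups[!small],
       unplaced = unlist(groups[small], use.names = FALSE))
}

#' Family-wise-error grouping LOD threshold
#'
#' A per-pair LOD threshold controls the error of a single linkage test;
#' grouping applies one test per marker pair, so with hundreds of thousands
#' of pairs a handful of spurious LOD > 3 edges is expected and, under
#' single-linkage closure, a single false edge merges two chromosomes. This
#' returns the Bonferroni-adjusted threshold at which the expected number of
#' false edges over all pairs is `fwer`: the chi-square(1) quantile at
#' `1 - fwer / choose(n, 2)`, divided by 2 ln 10.
#'
#' @param n_markers Number of markers entering grouping.
#' @param fwer Tolerated expected count of false linkage edges (default
#'   0.05).
#' @return A LOD threshold.
#' @export
grouping_lod <- function(n_markers, fwer = 0.05) {
  n_pairs <- choose(n_markers, 2)
  if (n_pairs < 1) return(0)
  stats::qchisq(1 - fwer / n_pairs, df = 1) / (2 * log(10))
}

#' Completed recombination-fraction matrix for a marker set
#'
#' In a CP family a maternal-only x paternal-only marker pair carries no
#' information on recombination (its direct estimate is rf = 0.5). For
#' ordering and distance accumulation, such missing entries are completed by
#' the shortest path through informative pairs, summed on the additive
#' Haldane scale (both-parents-heterozygous markers act as bridges), then
#' converted back to an rf. Informative direct estimates are kept as the
#' minimum of the direct value and the best path.
#'
#' @param tp All-pairs table from [two_point_table()].
#' @param ids Marker ids of one linkage group.
#' @return A symmetric rf matrix over `ids` with no uninformative holes
#'   (entries where no path exists stay at 0.5).
#' @export
completed_rf_matrix <- function(tp, ids) {
  rf <- tp$rf[ids, ids, drop = FALSE]
  inf <- tp$n_informative[ids, ids, drop = FALSE] > 0
  d <- haldane(pmin(rf, 0.495))
  edge <- which(inf & upper.tri(inf), arr.ind = TRUE)
  if (nrow(edge) == 0) return(rf)
  g <- igraph::graph_from_data_frame(
    data.frame(from = ids[edge[, 1]], to = ids[edge[, 2]],
               weight = d[edge]),
    directed = FALSE, vertices = data.frame(name = ids))
  sp <- igraph::distances(g)[ids, ids]
  d_completed <- pmin(ifelse(inf, d, Inf), sp)
  out <- matrix(0.5, length(ids), length(ids), dimnames = list(ids, ids))
  finite <- is.finite(d_completed)
  out[finite] <- haldane_inv(d_completed[finite])
  diag(out) <- 0
  out
}

# internal: sum of adjacent recombination fractions for an order
.sarf <- function(ord, rf) sum(rf[cbind(ord[-length(ord)], ord[-1])])

# internal: greedy chain extension from a given start marker
.greedy_chain <- function(start, rf, ids_order) {
  n <- nrow(rf)
  chain <- c(start)
  left <- start; right <- start
  remaining <- setdiff(seq_len(n), start)
  while (length(remaining)) {
    cand_l <- rf[left, remaining]
    cand_r <- rf[right, remaining]
    # best addition at either end; ties broken by marker id order
    bl <- min(cand_l); br <- min(cand_r)
    if (bl <= br) {
      pick <- remaining[which(cand_l == bl)]
      pick <- pick[order(ids_order[pick])][1]
      chain <- c(pick, chain); left <- pick
    } else {
      pick <- remaining[which(cand_r == br)]
      pick <- pick[order(ids_order[pick])][1]
      chain <- c(chain, pick); right <- pick
    }
    remaining <- setdiff(remaining, pick)
  }
  chain
}

# internal: single-marker reinsertion pass; moves any marker to its best
# position under `score` until the objective stops decreasing (repairs
# long-range misplacements that a width-3 window cannot reach)
.reinsert <- function(ord, score) {
  n <- length(ord)
  improved <- TRUE
  while (improved) {
    improved <- FALSE
    for (m in seq_len(n)) {
      marker <- ord[m]
      rest <- ord[-m]
      best_s <- score(ord); best_ord <- ord
      for (pos in seq_len(n)) {
        cand <- append(rest, marker, after = pos - 1)
        s <- score(cand)
        if (s < best_s - 1e-9) { best_s <- s; best_ord <- cand }
      }
      if (!identical(best_ord, ord)) { ord <- best_ord; improved <- TRUE }
    }
  }
  ord
}

# internal: 2-opt segment-reversal pass; undoes inverted blocks
.two_opt <- function(ord, score) {
  n <- length(ord)
  improved <- TRUE
  while (improved) {
    improved <- FALSE
    cur <- score(ord)
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        cand <- ord
        cand[i:j] <- rev(ord[i:j])
        s <- score(cand)
        if (s < cur - 1e-9) {
          ord <- cand; cur <- s; improved <- TRUE
        }
      }
    }
  }
  ord
}

# internal: contiguous-block reinsertion; moves displaced segments of
# length 2..max_block to their best position
.block_reinsert <- function(ord, score, max_block = 6) {
  n <- length(ord)
  improved <- TRUE
  while (improved) {
    improved <- FALSE
    for (len in 2:min(max_block, n - 1)) {
      for (i in seq_len(n - len + 1)) {
        block <- ord[i:(i + len - 1)]
        rest <- ord[-(i:(i + len - 1))]
        cur <- score(ord)
        best_ord <- ord
        for (pos in seq_len(length(rest) + 1)) {
          cand <- append(rest, block, after = pos - 1)
          s <- score(cand)
          if (s < cur - 1e-9) { cur <- s; best_ord <- cand }
        }
        if (!identical(best_ord, ord)) { ord <- best_ord; improved <- TRUE }
      }
    }
  }
  ord
}

# internal: 1-D principal-coordinate seed order (classical MDS of the
# Kosambi-transformed dissimilarity); a strong seed for 1-D map structure
.pcoa_order <- function(rf) {
  d <- kosambi(pmin(rf, 0.499))
  fit <- tryCatch(stats::cmdscale(stats::as.dist(d), k = 1),
                  error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  order(fit[, 1])
}

# internal: ripple refinement, permuting every sliding window of `window`
# markers until the objective stops decreasing
.ripple <- function(ord, score, window = 3) {
  n <- length(ord)
  if (n <= 2) return(ord)
  perms <- .permutations(window)
  improved <- TRUE
  while (improved) {
    improved <- FALSE
    for (i in seq_len(n - window + 1)) {
      idx <- i:(i + window - 1)
      best <- score(ord)
      best_ord <- ord
      for (p in seq_len(nrow(perms))) {
        cand <- ord
        cand[idx] <- ord[idx][perms[p, ]]
        s <- score(cand)
        if (s < best - 1e-9) {
          best <- s; best_ord <- cand
        }
      }
      if (!identical(best_ord, ord)) {
        ord <- best_ord
        improved <- TRUE
      }
    }
  }
  ord
}

## ---- weighted least-squares 1-D embedding of two-point distances ---------
#
# Marker positions are estimated by pooling every informative pairwise
# distance, not only adjacent ones: minimise over positions x
#   sum_{i<j} w_ij * (|x_i - x_j| - d_ij)^2
# with w_ij the inverse sampling variance of d_ij (delta method, using the
# observed Fisher information of rf at the MLE). Distances enter on the
# Haldane scale: pairwise rf estimates spanning many intervals compose
# without interference under the two-point Markov model, so only the
# Haldane transform makes them additive -- a sub-additive transform would
# systematically compress long-range distances and mislead the arrangement
# of weakly-joined blocks. Reported map intervals are converted to Kosambi
# units afterwards (see .ls_positions). Pairs with rf near 0.5 are
# censored (weight 0): their distance is unbounded. Given a candidate
# order the signs of (x_i - x_j) are fixed, so the minimiser solves a
# weighted-Laplacian linear system; the Cholesky factor is computed once
# per group and reused across all candidate orders during refinement.

.RF_CENSOR <- 0.45

# internal: Haldane distance and weight matrices for one group. Var(d) by
# the delta method, with Var(r) = 1 / observed Fisher information at the
# MLE (this downweights weakly-informative pair types, e.g.
# both-parents-heterozygous pairs in repulsion, automatically).
.pair_ls_data <- function(tp, ids) {
  rf <- tp$rf[ids, ids, drop = FALSE]
  nim <- tp$n_informative[ids, ids, drop = FALSE]
  info <- tp$info[ids, ids, drop = FALSE]
  d <- haldane(pmin(rf, 0.495))
  r <- pmin(pmax(rf, 0.005), 0.495)
  # dd/dr for Haldane is 100 / (1 - 2r); w = info / (dd/dr)^2
  w <- ifelse(nim > 0 & rf < .RF_CENSOR,
              info * ((1 - 2 * r) / 100)^2, 0)
  diag(w) <- 0
  list(d = d, w = w)
}

# internal: censored-pair data: pairs observed unlinked (rf at/above the
# censor) are one-sided evidence of *distance*. An arrangement that places
# such a pair close is penalised by the approximate -2 log-likelihood of
# observing rf >= 0.45 at the fitted separation (normal approximation,
# z capped at 5 so a single pair cannot dominate).
.pair_censor_data <- function(tp, ids) {
  rf <- tp$rf[ids, ids, drop = FALSE]
  nim <- tp$n_informative[ids, ids, drop = FALSE]
  sel <- which(nim > 0 & rf >= .RF_CENSOR & upper.tri(rf), arr.ind = TRUE)
  list(i = sel[, 1], j = sel[, 2], nim = nim[sel])
}

.censor_penalty <- function(x, cen) {
  if (!length(cen$i)) return(0)
  g <- abs(x[cen$i] - x[cen$j])
  r <- pmax(haldane_inv(g), 0.01)
  z <- pmax(0, .RF_CENSOR - r) / sqrt(r * (1 - r) / cen$nim)
  sum(pmin(z, 5)^2)
}

# internal: solver context with pre-factored Laplacian (gauge: x[1] = 0)
.ls_context <- function(dat) {
  w <- dat$w
  n <- nrow(w)
  L <- diag(rowSums(w)) - w
  L1 <- L[-1, -1, drop = FALSE]
  diag(L1) <- diag(L1) + 1e-8 * max(diag(L1), 1)
  ch <- chol(L1)
  list(d = dat$d, w = w, n = n, chol = ch)
}

# internal: solve positions and stress for a candidate order
.ls_solve <- function(ctx, ord) {
  rk <- integer(ctx$n); rk[ord] <- seq_len(ctx$n)
  S <- sign(outer(rk, rk, "-"))
  t_mat <- ctx$d * S
  c_vec <- rowSums(ctx$w * t_mat)
  x <- c(0, backsolve(ctx$chol, forwardsolve(t(ctx$chol), c_vec[-1])))
  res <- outer(x, x, "-") - t_mat
  stress <- sum((ctx$w * res^2)[upper.tri(res)])
  list(x = x, stress = stress)
}

# internal: alternate position solve and reordering-by-position until stable
.ls_fit <- function(ctx, ord, max_iter = 25) {
  for (k in seq_len(max_iter)) {
    sol <- .ls_solve(ctx, ord)
    new_ord <- order(sol$x)
    if (identical(new_ord, ord) || identical(new_ord, rev(ord))) break
    ord <- new_ord
  }
  sol <- .ls_solve(ctx, ord)
  list(ord = ord, x = sol$x, stress = sol$stress)
}

# internal: final positions for an ordered group. The embedding is solved
# on the additive Haldane scale. Pairs whose rf sits against the 0.45
# censor are kept only when their estimate fluctuated downward, which
# systematically shortens the longest spans; the fit is therefore repeated
# keeping only pairs whose *fitted* separation (pooled over many pairs, so
# nearly selection-free) is below `window_cm`. Each adjacent fitted
# interval is finally converted to Kosambi units through its
# interval-scale recombination fraction, the convention for reported maps.
.ls_positions <- function(tp, ord, window_cm = 60) {
  n <- length(ord)
  dat <- .pair_ls_data(tp, ord)
  if (.ls_disconnected(dat$w)) {
    rf_c <- completed_rf_matrix(tp, ord)
    dat <- list(d = haldane(pmin(rf_c, 0.495)),
                w = matrix(1, n, n) - diag(n))
  }
  x <- .ls_solve(.ls_context(dat), seq_len(n))$x
  for (iter in 1:2) {
    gap <- abs(outer(x, x, "-"))
    W <- window_cm
    repeat {
      w_try <- dat$w
      w_try[gap > W] <- 0
      if (!.ls_disconnected(w_try)) break
      W <- W * 2
    }
    x <- .ls_solve(.ls_context(list(d = dat$d, w = w_try)),
                   seq_len(n))$x
  }
  d_h <- pmax(diff(x), 0)
  c(0, cumsum(kosambi(haldane_inv(d_h))))
}

.permutations <- function(k) {
  if (k == 1) return(matrix(1))
  sub <- .permutations(k - 1)
  do.call(rbind, lapply(seq_len(k), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' Order the markers of a linkage group
#'
#' Candidate orders are seeded by greedy chain extension (adding the marker
#' with the smallest completed recombination fraction to either chain end)
#' from every possible start marker and by a 1-D principal-coordinate
#' embedding; each seed is polished by alternating weighted least-squares
#' position fits and reordering (see `completed_rf_matrix` and the embedding
#' notes in the source). The best candidate is refined by ripple passes
#' (permuting every sliding window of three markers) and single-marker
#' reinsertion moves, both scored by the least-squares stress, until the
#' stress stops decreasing. The orientation is normalised so the first
#' marker id sorts before the last.
#'
#' When `objective = "sarf"` the classic sum of adjacent recombination
#' fractions over the completed rf matrix is used as the score instead
#' (useful against exhaustive-search baselines on small groups).
#'
#' @param group Character vector of marker ids.
#' @param tp All-pairs table from [two_point_table()].
#' @param objective `"stress"` (weighted least-squares, default) or
#'   `"sarf"`.
#' @return Marker ids in map order.
#' @export
order_group <- function(group, tp, objective = c("stress", "sarf")) {
  objective <- match.arg(objective)
  ids <- sort(group)
  if (length(ids) <= 2) return(ids)
  n <- length(ids)
  rf_c <- completed_rf_matrix(tp, ids)

  ids_order <- seq_len(n)  # ids already sorted; index = id rank
  seeds <- lapply(seq_len(n), .greedy_chain, rf = rf_c,
                  ids_order = ids_order)
  pc <- .pcoa_order(rf_c)
  if (!is.null(pc)) seeds <- c(seeds, list(pc))

  if (objective == "sarf") {
    score <- function(ord) .sarf(ord, rf_c)
    ord <- seeds[[which.min(vapply(seeds, score, numeric(1)))]]
  } else {
    dat <- .pair_ls_data(tp, ids)
    if (.ls_disconnected(dat$w)) {
      # not enough well-measured pairs: fall back to completed distances
      # with uniform weights
      dat <- list(d = haldane(pmin(rf_c, 0.495)),
                  w = matrix(1, n, n) - diag(n))
    }
    ctx <- .ls_context(dat)
    cen <- .pair_censor_data(tp, ids)
    score <- function(o) {
      sol <- .ls_solve(ctx, o)
      sol$stress + .censor_penalty(sol$x, cen)
    }
    fits <- lapply(seeds, function(s) .ls_fit(ctx, s))
    ord <- fits[[which.min(vapply(fits, function(f) {
      f$stress + .censor_penalty(f$x, cen)
    }, numeric(1)))]]$ord
  }
  repeat {
    before <- score(ord)
    ord <- .reinsert(.ripple(ord, score), score)
    ord <- .block_reinsert(.two_opt(ord, score), score)
    if (objective == "stress") ord <- .ls_fit(ctx, ord)$ord
    if (score(ord) >= before - 1e-9) break
  }
  if (ids[ord[1]] > ids[ord[length(ord)]]) ord <- rev(ord)
  ids[ord]
}

# internal: is the positive-weight graph disconnected?
.ls_disconnected <- function(w) {
  n <- nrow(w)
  seen <- logical(n); seen[1] <- TRUE
  queue <- 1L
  while (length(queue)) {
    k <- queue[1]; queue <- queue[-1]
    nb <- which(w[k, ] > 0 & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  !all(seen)
}

#' Build a genetic map from ordered linkage groups
#'
#' With `method = "ls"` (default) marker positions within each group come
#' from the weighted least-squares embedding of all informative two-point
#' Kosambi distances in the given order (the estimator behind
#' [order_group()]); pooling every pair rather than only adjacent ones
#' keeps interval noise from accumulating along the chain. With
#' `method = "adjacent"` positions are cumulative Kosambi distances over
#' the adjacent completed rf estimates only. In both cases the first marker
#' of each group sits at 0 cM; an adjacent rf still at 0.5 after completion
#' (no informative path at all) is capped at 0.499 with a warning.
#'
#' @param orders Named list of ordered marker-id vectors (one per group).
#' @param tp All-pairs table from [two_point_table()].
#' @param markers Optional marker table (`id`, `scaffold`, `pos_bp`) used to
#'   carry physical coordinates into the map.
#' @param method `"ls"` or `"adjacent"`.
#' @return A `"genetic_map"` data.frame: `group`, `marker`, `scaffold`,
#'   `pos_bp`, `cM`.
#' @export
build_map <- function(orders, tp, markers = NULL,
                      method = c("ls", "adjacent")) {
  method <- match.arg(method)
  rows <- lapply(names(orders), function(gname) {
    ord <- orders[[gname]]
    if (length(ord) == 1) {
      cm <- 0
    } else if (method == "ls") {
      cm <- .ls_positions(tp, ord)
    } else {
      rf_c <- completed_rf_matrix(tp, ord)
      rfs <- rf_c[cbind(ord[-length(ord)], ord[-1])]
      if (any(rfs >= 0.5)) {
        warning(sum(rfs >= 0.5), " adjacent rf estimate(s) of 0.5 in group ",
                gname, "; capped at 0.499")
        rfs <- pmin(rfs, 0.499)
      }
      cm <- c(0, cumsum(kosambi(rfs)))
    }
    data.frame(group = gname, marker = ord, cM = cm, stringsAsFactors = FALSE)
  })
  map <- do.call(rbind, rows)
  if (!is.null(markers)) {
    mi <- match(map$marker, markers$id)
    map$scaffold <- markers$scaffold[mi]
    map$pos_bp <- markers$pos_bp[mi]
    map <- map[, c("group", "marker", "scaffold", "pos_bp", "cM")]
  }
  class(map) <- c("genetic_map", "data.frame")
  map
}

#' Per-group and overall map statistics
#'
#' For each linkage group: marker count, total length, marker density
#' (length / (n - 1), the mean adjacent interval) and the largest adjacent
#' interval. Overall, both the mean of per-group densities and the pooled
#' total length / total intervals are reported, since the two aggregates
#' differ.
#'
#' @param map A `"genetic_map"`.
#' @return List: `per_group` data.frame and `overall` list.
#' @export
map_summary <- function(map) {
  per <- do.call(rbind, lapply(split(map, map$group), function(g) {
    n <- nrow(g)
    len <- max(g$cM) - min(g$cM)
    gaps <- if (n > 1) diff(sort(g$cM)) else NA_real_
    data.frame(group = g$group[1], n_markers = n, length_cM = len,
               density_cM = if (n > 1) len / (n - 1) else NA_real_,
               largest_interval_cM = if (n > 1) max(gaps) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  n_int <- sum(per$n_markers - 1)
  list(per_group = per,
       overall = list(
         n_groups = nrow(per),
         n_markers = sum(per$n_markers),
         total_length_cM = sum(per$length_cM),
         mean_group_density_cM = mean(per$density_cM, na.rm = TRUE),
         pooled_density_cM = if (n_int > 0) sum(per$length_cM) / n_int
                             else NA_real_))
}
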