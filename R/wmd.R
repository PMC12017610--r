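#' Exact minimum-cost transport between two discrete mass distributions
#'
#' Solves the balanced transportation problem exactly by successive
#' shortest augmenting paths (Bellman-Ford on the bipartite residual
#' graph) over integer mass units. Real-valued masses are handled by
#' scaling each side to a common integer total, so inputs whose masses are
#' rational (e.g. bag-of-words counts divided by document length) are
#' solved without rounding error.
#'
#' @param supply Nonnegative numeric vector (integer counts recommended).
#' @param demand Nonnegative numeric vector; `sum(supply)` and
#'   `sum(demand)` need not match — both sides are normalized to total
#'   mass 1.
#' @param cost Cost matrix, `length(supply)` x `length(demand)`.
#' @return List with `cost` (minimal total cost for unit total mass) and
#'   `plan` (the optimal transport matrix, summing to 1).
#' @export
min_cost_transport <- function(supply, demand, cost) {
  stopifnot(all(supply >= 0), all(demand >= 0),
            sum(supply) > 0, sum(demand) > 0,
            nrow(cost) == length(supply), ncol(cost) == length(demand))
  keep_i <- supply > 0; keep_j <- demand > 0
  supply <- supply[keep_i]; demand <- demand[keep_j]
  cost_k <- cost[keep_i, keep_j, drop = FALSE]
  si <- to_integer_units(supply)
  dj <- to_integer_units(demand)
  # common total: supply in units of 1/(S*D), demand likewise
  s_units <- si$units * sum(dj$units)
  d_units <- dj$units * sum(si$units)
  g <- Reduce(gcd2, c(s_units, d_units))
  s_units <- s_units / g
  d_units <- d_units / g
  total <- sum(s_units)

  fl <- ssp_transport(s_units, d_units, cost_k)
  plan_full <- matrix(0, length(keep_i), length(keep_j))
  plan_full[keep_i, keep_j] <- fl / total
  list(cost = sum(fl * cost_k) / total, plan = plan_full)
}

# rationalize nonnegative masses to integer units (denominator up to 1e6)
to_integer_units <- function(x) {
  if (all(abs(x - round(x)) < 1e-9)) {
    u <- round(x)
  } else {
    scale <- 1e6 / max(x)
    u <- round(x * scale)
    u[x > 0 & u == 0] <- 1
  }
  g <- Reduce(gcd2, u[u > 0])
  list(units = u / g)
}

gcd2 <- function(a, b) {
  while (b > 0) { r <- a %% b; a <- b; b <- r }
  a
}

# successive-shortest-path min-cost flow on the bipartite transport graph;
# s_units/d_units integer, equal totals; returns flow matrix in units
ssp_transport <- function(s_units, d_units, cost) {
  m <- length(s_units); n <- length(d_units)
  flow <- matrix(0, m, n)
  rs <- s_units; rd <- d_units
  big <- .Machine$double.xmax / 4
  while (sum(rs) > 0) {
    dist_s <- ifelse(rs > 0, 0, big)
    dist_d <- rep(big, n)
    par_d <- rep(NA_integer_, n)   # forward arc par_d[j] -> j on best path
    par_s <- rep(NA_integer_, m)   # backward arc from demand par_s[i] to supply i
    # Bellman-Ford: alternate forward (s->d) and backward (d->s) relaxations;
    # a shortest alternating path has at most m+n arcs
    for (round in seq_len(m + n + 1L)) {
      changed <- FALSE
      for (j in seq_len(n)) {
        cand <- dist_s + cost[, j]
        i_best <- which.min(cand)
        if (cand[i_best] + 1e-12 < dist_d[j]) {
          dist_d[j] <- cand[i_best]; par_d[j] <- i_best; changed <- TRUE
        }
      }
      for (i in seq_len(m)) {
        has <- which(flow[i, ] > 0)
        if (length(has)) {
          cand <- dist_d[has] - cost[i, has]
          k <- which.min(cand)
          if (cand[k] + 1e-12 < dist_s[i]) {
            dist_s[i] <- cand[k]; par_s[i] <- has[k]; changed <- TRUE
          }
        }
      }
      if (!changed) break
    }
    targets <- which(rd > 0)
    j <- targets[which.min(dist_d[targets])]
    if (dist_d[j] >= big) stop("transport: no augmenting path")
    # backtrack alternating path from demand j to a source supply node
    fwd <- matrix(0L, 0, 2); bwd <- matrix(0L, 0, 2)
    bott <- rd[j]
    jj <- j
    src <- NA_integer_
    repeat {
      ii <- par_d[jj]
      fwd <- rbind(fwd, c(ii, jj))
      if (is.na(par_s[ii])) {       # initial node: a supply with rs > 0
        bott <- min(bott, rs[ii])
        src <- ii
        break
      }
      jb <- par_s[ii]
      bott <- min(bott, flow[ii, jb])
      bwd <- rbind(bwd, c(ii, jb))
      jj <- jb
    }
    for (r in seq_len(nrow(fwd)))
      flow[fwd[r, 1], fwd[r, 2]] <- flow[fwd[r, 1], fwd[r, 2]] + bott
    for (r in seq_len(nrow(bwd)))
      flow[bwd[r, 1], bwd[r, 2]] <- flow[bwd[r, 1], bwd[r, 2]] - bott
    rs[src] <- rs[src] - bott
    rd[j] <- rd[j] - bott
  }
  flow
}

#' Word mover's distance between two token lists
#'
#' Both documents are reduced to normalized bag-of-words mass distributions
#' over their in-vocabulary tokens (each document's token counts divided by
#' its in-vocabulary length); the distance is the minimal cumulative cost of
#' transporting one distribution onto the other, with Euclidean distance
#' between embedding vectors as the ground cost. Symmetric in its
#' arguments; zero iff the two distributions coincide. Out-of-vocabulary
#' tokens are dropped and counted.
#'
#' @param doc Character vector of tokens (e.g. a participant's retelling).
#' @param ref Character vector of tokens (e.g. the reference story).
#' @param embeddings An [embedding_table()].
#' @return The distance (nonnegative scalar) with attributes `n_oov_doc`
#'   and `n_oov_ref`; `NA` (with the attributes) when either side is empty
#'   after out-of-vocabulary filtering.
#' @export
word_movers_distance <- function(doc, ref, embeddings) {
  stopifnot(inherits(embeddings, "embedding_table"))
  vocab <- rownames(embeddings)
  doc_in <- doc[doc %in% vocab]
  ref_in <- ref[ref %in% vocab]
  n_oov_doc <- length(doc) - length(doc_in)
  n_oov_ref <- length(ref) - length(ref_in)
  if (length(doc_in) == 0 || length(ref_in) == 0) {
    return(structure(NA_real_, n_oov_doc = n_oov_doc, n_oov_ref = n_oov_ref))
  }
  tc <- table(doc_in); rc <- table(ref_in)
  wi <- names(tc); wj <- names(rc)
  ei <- embeddings[wi, , drop = FALSE]
  ej <- embeddings[wj, , drop = FALSE]
  # pairwise Euclidean distances
  cross <- ei %*% t(ej)
  d2 <- outer(rowSums(ei^2), rowSums(ej^2), `+`) - 2 * cross
  cost <- sqrt(pmax(d2, 0))
  cost[outer(wi, wj, `==`)] <- 0   # exact zero for identical words
  res <- min_cost_transport(as.numeric(tc), as.numeric(rc), cost)
  structure(res$cost, n_oov_doc = n_oov_doc, n_oov_ref = n_oov_ref)
}
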