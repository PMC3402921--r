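#' Exact minimum-barrier direct pathway
#'
#' Solves the restricted problem exactly: among all *direct* pathways from
#' `A` to `B` (intermediates use only base pairs of `A` and `B`), find one
#' whose maximum structure energy is minimal. The state space is the set of
#' valid (disjoint, non-crossing) subsets of the pair union; edges are
#' single base-pair additions/deletions; the objective is the bottleneck
#' (minimax) node energy including both endpoints. Solved by sweeping
#' states in order of increasing energy with a union-find until start and
#' end connect, which is exact for the bottleneck objective; the
#' certificate chain is the shortest path inside the threshold subgraph,
#' with deterministic tie-breaks (fewer steps, then lexicographic state
#' order).
#'
#' The full problem over indirect pathways is NP-hard; this solver is an
#' independent oracle for small instances (at most `cap` pairs in the
#' union), used to bound what the evolutionary search should achieve.
#'
#' @param model An `energy_model`.
#' @param x An `rna_seq`.
#' @param A,B Endpoint `rna_structure`s.
#' @param cap Maximum size of the pair union (default 16; state space
#'   `2^cap`).
#' @return A list with `barrier` (kcal/mol), `saddle_energy`, and `chain`
#'   (an optimal direct `action_chain`).
#' @export
exact_direct_barrier <- function(model, x, A, B, cap = 16L) {
  U <- unique(rbind(unclass(A)[, , drop = FALSE], unclass(B)[, , drop = FALSE]))
  P <- nrow(U)
  if (P > cap) stop("pair union has ", P, " pairs; exceeds cap ", cap)
  n <- attr(A, "n")
  if (P == 0L) {
    return(list(barrier = 0, saddle_energy = evaluate_energy(model, x, A),
                chain = new_chain(NULL, A, B)))
  }
  # pairwise incompatibility masks (shared position or crossing)
  conf <- integer(P)
  for (r in seq_len(P)) for (s in seq_len(P)) {
    if (r == s) next
    i1 <- U[r, 1L]; j1 <- U[r, 2L]; i2 <- U[s, 1L]; j2 <- U[s, 2L]
    shares <- length(intersect(c(i1, j1), c(i2, j2))) > 0L
    crosses <- (i1 < i2 && i2 < j1 && j1 < j2) || (i2 < i1 && i1 < j2 && j2 < j1)
    if (shares || crosses) conf[r] <- conf[r] + bitwShiftL(1L, s - 1L)
  }
  nsub <- bitwShiftL(1L, P)
  # lowest-bit index (trailing zeros + 1) of every subset
  lb <- rep(1L, nsub - 1L)
  for (k in seq_len(P - 1L)) {
    step <- bitwShiftL(1L, k)
    if (step > nsub - 1L) break
    lb[seq.int(step, nsub - 1L, by = step)] <- k + 1L
  }
  valid <- logical(nsub)           # valid[s + 1] for subset s
  valid[1L] <- TRUE
  for (s in seq_len(nsub - 1L)) {
    r <- lb[s]
    rest <- s - bitwShiftL(1L, r - 1L)
    valid[s + 1L] <- valid[rest + 1L] && bitwAnd(conf[r], rest) == 0L
  }
  states <- which(valid) - 1L
  subset_db <- function(s) {
    ch <- rep(".", n)
    for (r in seq_len(P)) {
      if (bitwAnd(s, bitwShiftL(1L, r - 1L)) != 0L) {
        ch[U[r, 1L]] <- "("
        ch[U[r, 2L]] <- ")"
      }
    }
    paste(ch, collapse = "")
  }
  dbs <- vapply(states, subset_db, character(1))
  E <- evaluate_many(model, x, dbs)
  id_of <- integer(nsub)           # subset -> index in `states`
  id_of[states + 1L] <- seq_along(states)
  mask_of <- function(S) {
    ks <- pair_keys(S)
    ku <- U[, 1L] * (n + 1L) + U[, 2L]
    sum(bitwShiftL(1L, which(ku %in% ks) - 1L))
  }
  a_id <- id_of[mask_of(A) + 1L]
  b_id <- id_of[mask_of(B) + 1L]
  stopifnot(a_id > 0L, b_id > 0L)

  # sweep states in energy order (ties: smaller subset first), union-find
  ord <- order(E, states)
  parent <- seq_along(states)
  find <- function(v) {
    while (parent[v] != v) {
      parent[v] <<- parent[parent[v]]
      v <- parent[v]
    }
    v
  }
  added <- logical(length(states))
  saddle <- NA_real_
  for (idx in ord) {
    s <- states[idx]
    added[idx] <- TRUE
    for (r in seq_len(P)) {
      nb <- bitwXor(s, bitwShiftL(1L, r - 1L))
      if (nb < nsub && valid[nb + 1L]) {
        nb_idx <- id_of[nb + 1L]
        if (added[nb_idx]) {
          ra <- find(idx); rb <- find(nb_idx)
          if (ra != rb) parent[ra] <- rb
        }
      }
    }
    if (added[a_id] && added[b_id] && find(a_id) == find(b_id)) {
      saddle <- E[idx]
      break
    }
  }
  # certificate: BFS shortest path within the threshold subgraph
  thr <- saddle + 1e-9
  inside <- E <= thr & added
  prev <- rep(NA_integer_, length(states))
  queue <- a_id
  prev[a_id] <- 0L
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    if (v == b_id) break
    s <- states[v]
    for (r in seq_len(P)) {          # ascending bit order: deterministic
      nb <- bitwXor(s, bitwShiftL(1L, r - 1L))
      if (valid[nb + 1L]) {
        w <- id_of[nb + 1L]
        if (inside[w] && is.na(prev[w])) {
          prev[w] <- v
          queue <- c(queue, w)
        }
      }
    }
  }
  path <- b_id
  while (prev[path[1L]] != 0L) path <- c(prev[path[1L]], path)
  rows <- NULL
  for (t in seq_len(length(path) - 1L)) {
    d <- bitwXor(states[path[t]], states[path[t + 1L]])
    r <- which(bitwAnd(d, bitwShiftL(1L, seq_len(P) - 1L)) != 0L)
    op <- if (bitwAnd(states[path[t + 1L]], d) != 0L) 1L else -1L
    rows <- rbind(rows, c(op, U[r, 1L], U[r, 2L]))
  }
  chain <- new_chain(rows, A, B)
  list(barrier = saddle - E[a_id], saddle_energy = saddle, chain = chain)
}
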