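#' Mutation context for the pathway operators
#'
#' Bundles the per-instance data the mutation operators share: the
#' sequence, the endpoint structures, the enumerated stack set, the set of
#' admissible base pairs, and the control knobs.
#'
#' @param x An `rna_seq`.
#' @param A,B Endpoint `rna_structure`s.
#' @param min_stack_len Minimum stack length for the stack set (default 4).
#' @param min_hairpin Minimum hairpin loop (default 3).
#' @param retry_limit Failed draws tolerated per offspring attempt before
#'   giving up (default 50).
#' @param beta Exponent of the biased position weights (default 1, linear).
#' @return A list of class `mutation_context`.
#' @export
mutation_context <- function(x, A, B, min_stack_len = 4L, min_hairpin = 3L,
                             retry_limit = 50L, beta = 1) {
  n <- seq_len_of(x)
  ij <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  keep <- vapply(seq_len(nrow(ij)), function(r) {
    pair_allowed(x, ij[r, 1L], ij[r, 2L], min_hairpin)
  }, logical(1))
  structure(list(
    x = x, A = A, B = B, n = n,
    allowed_pairs = unname(ij[keep, , drop = FALSE]),
    sta = enumerate_stacks(x, min_stack_len, min_hairpin),
    retry_limit = as.integer(retry_limit),
    beta = beta
  ), class = "mutation_context")
}

chain_ok <- function(ctx, mat) validate_chain(ctx$A, ctx$B, mat)$ok

# structure (pair table) after the first `pos` actions of `mat`
pt_after <- function(ctx, mat, pos) {
  pt <- pair_table(ctx$A)
  if (pos >= 1L) for (t in seq_len(pos)) {
    pt <- apply_action_pt(pt, mat[t, 1L], mat[t, 2L], mat[t, 3L])
    if (is.character(pt)) stop("invalid chain prefix at step ", t)
  }
  pt
}

# remove action t1 and re-insert it after action t2 (t2 in 0..m, t2 != t1,
# indices refer to the original ordering)
reloc_rows <- function(mat, t1, t2) {
  row <- mat[t1, , drop = FALSE]
  rest <- mat[-t1, , drop = FALSE]
  pos <- t2 - (t1 <= t2)        # insertion point in the reduced sequence
  rbind(rest[seq_len(pos), , drop = FALSE], row,
        if (pos < nrow(rest)) rest[(pos + 1L):nrow(rest), , drop = FALSE])
}

insert_rows <- function(mat, after, row) {
  rbind(mat[seq_len(after), , drop = FALSE], row,
        if (after < nrow(mat)) mat[(after + 1L):nrow(mat), , drop = FALSE])
}

#' Feasible relocation interval of an action
#'
#' For a valid chain and a position `t1`, computes the contiguous interval
#' of target positions `t2` around `t1` such that removing action `t1` and
#' re-inserting it after action `t2` yields a valid chain. Validity is
#' established by full revalidation at each candidate, scanning outward
#' from `t1` and stopping at the first infeasible position in each
#' direction.
#'
#' @param A,B Endpoint structures.
#' @param chain An `action_chain` (or m x 3 action matrix).
#' @param t1 Position of the action to relocate, `1 <= t1 <= m`.
#' @return Integer vector of feasible `t2` values (possibly including
#'   `t1 - 1`, the identity relocation); empty when `m < 2`.
#' @export
feasible_interval <- function(A, B, chain, t1) {
  m <- nrow(chain)
  if (m < 2L) return(integer(0))
  lo <- t1 - 1L                  # identity: always feasible
  while (lo - 1L >= 0L) {
    if (!validate_chain(A, B, reloc_rows(chain, t1, lo - 1L))$ok) break
    lo <- lo - 1L
  }
  hi <- t1 - 1L
  cand <- t1 + 1L
  while (cand <= m) {
    if (!validate_chain(A, B, reloc_rows(chain, t1, cand))$ok) break
    hi <- cand
    cand <- cand + 1L
  }
  out <- lo:hi
  out[out != t1]
}

#' Biased choice of a position in an interval
#'
#' Draws an index from `l..u` with strictly monotone weights:
#' `front_loaded` weights position `t` proportionally to `(u - t + 1)^beta`
#' (earlier positions more likely), `back_loaded` proportionally to
#' `(t - l + 1)^beta`. Used to place additions early and deletions late,
#' which tends to keep intermediate structures stable.
#'
#' @param l,u Interval bounds, `l <= u`.
#' @param mode `"front_loaded"` or `"back_loaded"`.
#' @param beta Weight exponent (default 1, linear weights).
#' @return One index in `l..u`.
#' @export
biased_index_choice <- function(l, u, mode = c("front_loaded", "back_loaded"),
                                beta = 1) {
  mode <- match.arg(mode)
  stopifnot(l <= u)
  cand <- l:u
  w <- if (mode == "front_loaded") (u - cand + 1)^beta else (cand - l + 1)^beta
  cand[sample.int(length(cand), 1L, prob = w)]
}

# biased choice over an arbitrary (contiguous) candidate vector
biased_pick <- function(cand, mode, beta) {
  if (length(cand) == 1L) return(cand)
  w <- if (mode == "front_loaded") {
    (length(cand):1)^beta
  } else {
    (1:length(cand))^beta
  }
  cand[sample.int(length(cand), 1L, prob = w)]
}

uniform_pick <- function(v) v[sample.int(length(v), 1L)]

as_offspring <- function(ctx, mat) new_chain(mat, ctx$A, ctx$B)

#' M1: relocate one action
#'
#' Picks an action uniformly at random, computes its feasible relocation
#' interval, and draws the target position with front-loaded weights for
#' additions and back-loaded weights for deletions.
#'
#' @param p An `action_chain`.
#' @param ctx A `mutation_context`.
#' @return A valid offspring `action_chain`, or `NULL` when no offspring
#'   could be produced.
#' @export
m1_move <- function(p, ctx) {
  m <- nrow(p)
  if (m < 2L) return(NULL)
  for (k in seq_len(ctx$retry_limit)) {
    t1 <- sample.int(m, 1L)
    iv <- feasible_interval(ctx$A, ctx$B, p, t1)
    if (!length(iv)) next
    mode <- if (p[t1, 1L] > 0L) "front_loaded" else "back_loaded"
    t2 <- biased_pick(iv, mode, ctx$beta)
    return(as_offspring(ctx, reloc_rows(p, t1, t2)))
  }
  NULL
}

#' M2: swap two actions
#'
#' Swaps two uniformly chosen positions; invalid draws are restarted up to
#' the retry limit.
#'
#' @inheritParams m1_move
#' @return A valid offspring `action_chain`, or `NULL`.
#' @export
m2_swap <- function(p, ctx) {
  m <- nrow(p)
  if (m < 2L) return(NULL)
  for (k in seq_len(ctx$retry_limit)) {
    t12 <- sort(sample.int(m, 2L))
    mat <- p
    mat[t12, ] <- mat[rev(t12), ]
    if (chain_ok(ctx, mat)) return(as_offspring(ctx, mat))
  }
  NULL
}

# insert a complementary pair of actions: `row` (op,i,j) right after `pos`,
# and its complement at a back-loaded feasible position further on;
# returns the new matrix or NULL
insert_complementary <- function(ctx, mat, pos, op, i, j, beta = ctx$beta) {
  m1 <- insert_rows(mat, pos, c(op, i, j))
  comp <- c(-op, i, j)
  feas <- integer(0)
  for (q in (pos + 1L):nrow(m1)) {
    if (validate_chain(ctx$A, ctx$B, insert_rows(m1, q, comp))$ok) {
      feas <- c(feas, q)
    } else if (length(feas)) {
      break                     # contiguous block around the first feasible
    }
  }
  if (!length(feas)) return(NULL)
  insert_rows(m1, biased_pick(feas, "back_loaded", beta), comp)
}

#' M3: insert a complementary pair of actions
#'
#' Introduces an indirect detour: an addition `add(i,j)` after a uniformly
#' chosen step together with its complementary deletion later (sign
#' `"add_then_del"`), or a temporary deletion of an existing pair with its
#' re-addition later (`"del_then_add"`). The position of the complementary
#' action is drawn back-loaded, so a formed pair is unlikely to be deleted
#' soon after its formation.
#'
#' @inheritParams m1_move
#' @param sign `"add_then_del"` or `"del_then_add"`.
#' @return A valid offspring `action_chain` of length `m + 2`, or `NULL`.
#' @export
m3_insert_pair <- function(p, ctx, sign = c("add_then_del", "del_then_add")) {
  sign <- match.arg(sign)
  m <- nrow(p)
  if (m < 1L) return(NULL)
  for (k in seq_len(ctx$retry_limit)) {
    t1 <- sample.int(m, 1L)
    pt <- pt_after(ctx, p, t1)
    if (sign == "add_then_del") {
      ok <- vapply(seq_len(nrow(ctx$allowed_pairs)), function(r) {
        classify_pair_pt(pt, ctx$allowed_pairs[r, 1L],
                         ctx$allowed_pairs[r, 2L]) == "ok"
      }, logical(1))
      if (!any(ok)) next
      cand <- ctx$allowed_pairs[ok, , drop = FALSE]
      pick <- cand[sample.int(nrow(cand), 1L), ]
      mat <- insert_complementary(ctx, p, t1, 1L, pick[1L], pick[2L])
    } else {
      i <- which(pt > seq_along(pt))
      if (!length(i)) next
      ii <- uniform_pick(i)
      mat <- insert_complementary(ctx, p, t1, -1L, ii, pt[ii])
    }
    if (!is.null(mat)) return(as_offspring(ctx, mat))
  }
  NULL
}

# ensure action (op,i,j) occurs right after `pos` in `mat`: relocate a later
# occurrence if present, otherwise insert it with its complement; returns
# the new matrix or NULL on failure
force_action_after <- function(ctx, mat, pos, op, i, j) {
  later <- which(mat[, 1L] == op & mat[, 2L] == i & mat[, 3L] == j)
  later <- later[later > pos]
  if (length(later)) {
    cand <- reloc_rows(mat, later[1L], pos)
    if (chain_ok(ctx, cand)) return(cand)
    return(NULL)
  }
  insert_complementary(ctx, mat, pos, op, i, j)
}

#' M4: force the formation of a compatible stack
#'
#' Chooses a step `t` uniformly and a stack compatible with the structure
#' at `t` (with at least one missing pair), then forces the missing pairs
#' to form immediately after `t`, innermost pair first: an addition already
#' present later in the chain is relocated forward; otherwise a
#' complementary add/del pair is inserted.
#'
#' @inheritParams m1_move
#' @return A valid offspring `action_chain`, or `NULL`.
#' @export
m4_force_stack <- function(p, ctx) {
  m <- nrow(p)
  if (m < 1L || !length(ctx$sta)) return(NULL)
  for (k in seq_len(ctx$retry_limit)) {
    t <- sample.int(m, 1L)
    pt <- pt_after(ctx, p, t)
    S_t <- structure_from_pt(pt)
    ok <- vapply(ctx$sta, function(st) {
      stack_compatible(st, S_t) && any(pt[st[, 1L]] != st[, 2L])
    }, logical(1))
    if (!any(ok)) next
    st <- ctx$sta[[uniform_pick(which(ok))]]
    mat <- p
    pos <- t
    failed <- FALSE
    for (r in rev(seq_len(nrow(st)))) {        # innermost first
      i <- st[r, 1L]; j <- st[r, 2L]
      cur <- pt_after(ctx, mat, pos)
      if (cur[i] == j) next                     # already formed here
      mat2 <- force_action_after(ctx, mat, pos, 1L, i, j)
      if (is.null(mat2)) { failed <- TRUE; break }
      mat <- mat2
      pos <- pos + 1L
    }
    if (!failed && chain_ok(ctx, mat)) return(as_offspring(ctx, mat))
  }
  NULL
}

#' M5: convert between incompatible stacks
#'
#' Anchors at a uniformly chosen deletion action `a_t` and a stack that is
#' incompatible with the structure at `t`, then forces that stack to form
#' right after `t` while deleting the pairs that block it: compatible
#' members are placed as in M4; for an incompatible member every blocking
#' pair of the current structure is deleted beforehand (relocating an
#' existing deletion forward, or inserting a complementary del/add pair),
#' innermost blocker first. The offspring simulates the cooperative
#' destruction of one stack and formation of an incompatible one.
#'
#' @inheritParams m1_move
#' @return A valid offspring `action_chain`, or `NULL` (in particular when
#'   the chain has no deletion action).
#' @export
m5_convert_stacks <- function(p, ctx) {
  dels <- which(p[, 1L] < 0L)
  if (!length(dels) || !length(ctx$sta)) return(NULL)
  for (k in seq_len(ctx$retry_limit)) {
    t <- uniform_pick(dels)
    pt <- pt_after(ctx, p, t)
    S_t <- structure_from_pt(pt)
    bad <- vapply(ctx$sta, function(st) !stack_compatible(st, S_t), logical(1))
    if (!any(bad)) next
    st <- ctx$sta[[uniform_pick(which(bad))]]
    mat <- p
    pos <- t
    failed <- FALSE
    # members are placed outermost-first: the outer pairs of the incoming
    # stack nest around the remains of the outgoing one, so destruction
    # and formation can interleave instead of melting everything first
    for (r in seq_len(nrow(st))) {
      i <- st[r, 1L]; j <- st[r, 2L]
      cur <- pt_after(ctx, mat, pos)
      if (cur[i] == j) next
      if (classify_pair_pt(cur, i, j) != "ok") {
        # delete every blocking pair of the current structure first,
        # innermost blocker first
        blockers <- blocking_pairs(cur, i, j)
        if (nrow(blockers)) {
          ord <- order(-blockers[, 1L])         # larger i* = more inner
          for (b in ord) {
            bi <- blockers[b, 1L]; bj <- blockers[b, 2L]
            cur2 <- pt_after(ctx, mat, pos)
            if (cur2[bi] != bj) next            # already gone
            mat2 <- force_action_after(ctx, mat, pos, -1L, bi, bj)
            if (is.null(mat2)) { failed <- TRUE; break }
            mat <- mat2
            pos <- pos + 1L
          }
        }
        if (failed) break
      }
      mat2 <- force_action_after(ctx, mat, pos, 1L, i, j)
      if (is.null(mat2)) { failed <- TRUE; break }
      mat <- mat2
      pos <- pos + 1L
    }
    if (!failed && chain_ok(ctx, mat)) return(as_offspring(ctx, mat))
  }
  NULL
}

# pairs of the structure (pair table) that conflict with or cross (i, j)
blocking_pairs <- function(pt, i, j) {
  prs <- which(pt > seq_along(pt))
  out <- NULL
  for (a in prs) {
    b <- pt[a]
    conflicts <- a == i || a == j || b == i || b == j
    crosses <- (a < i && i < b && b < j) || (i < a && a < j && j < b)
    if (conflicts || crosses) out <- rbind(out, c(a, b))
  }
  if (is.null(out)) matrix(integer(0), ncol = 2L) else out
}

# the five strategies, addressed by name in the evolutionary loop
mutation_strategies <- function() {
  list(
    M1 = m1_move,
    M2 = m2_swap,
    M3 = function(p, ctx) {
      sign <- if (stats::runif(1) < 0.5) "add_then_del" else "del_then_add"
      m3_insert_pair(p, ctx, sign)
    },
    M4 = m4_force_stack,
    M5 = m5_convert_stacks
  )
}
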