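#' Construct an action
#'
#' An action adds or deletes one base pair of an intermediate structure.
#' An action is *direct* with respect to endpoints `(A, B)` when its pair
#' belongs to the union of their pair sets, and *indirect* otherwise.
#'
#' @param kind `"add"` or `"del"`.
#' @param i,j The base pair, `i < j`.
#' @return A named integer vector `c(op, i, j)` with `op = +1` for add,
#'   `-1` for del.
#' @export
action <- function(kind = c("add", "del"), i, j) {
  kind <- match.arg(kind)
  stopifnot(i < j)
  c(op = if (kind == "add") 1L else -1L, i = as.integer(i), j = as.integer(j))
}

# a chain is an m x 3 integer matrix (op, i, j) with endpoint structures
# attached; op +1 = add, -1 = del
new_chain <- function(mat, A, B) {
  if (is.null(mat) || length(mat) == 0L) mat <- matrix(integer(0), ncol = 3L)
  mat <- matrix(as.integer(mat), ncol = 3L)
  dimnames(mat) <- list(NULL, c("op", "i", "j"))
  structure(mat, A = A, B = B, class = "action_chain")
}

chain_m <- function(chain) nrow(chain)

#' @export
print.action_chain <- function(x, ...) {
  cat("Action chain of", nrow(x), "actions\n")
  if (nrow(x)) {
    lab <- paste0(ifelse(x[, 1L] > 0L, "add", "del"),
                  "(", x[, 2L], ",", x[, 3L], ")")
    cat(paste(lab, collapse = " "), "\n")
  }
  invisible(x)
}

#' @export
format.action_chain <- function(x, ...) {
  if (!nrow(x)) return(character(0))
  paste0(ifelse(x[, 1L] > 0L, "add", "del"), "(", x[, 2L], ",", x[, 3L], ")")
}

#' Apply one action to a structure
#'
#' @param S An `rna_structure`.
#' @param a An action from [action()].
#' @return The resulting `rna_structure`, differing from `S` by exactly the
#'   one pair.
#' @details Raises a condition of class `stackpath_conflict` when an added
#'   pair touches an occupied position or a deleted pair is absent, and
#'   `stackpath_clash` when an added pair would cross an existing pair.
#' @export
apply_action <- function(S, a) {
  pt <- pair_table(S)
  pt2 <- apply_action_pt(pt, a[1L], a[2L], a[3L])
  if (is.character(pt2)) {
    cls <- if (pt2 == "clash") "stackpath_clash" else "stackpath_conflict"
    stop(errorCondition(
      sprintf("%s(%d,%d) %ss with structure", if (a[1L] > 0L) "add" else "del",
              a[2L], a[3L], pt2),
      class = c(cls, "error", "condition")))
  }
  structure_from_pt(pt2)
}

# pair-table fast path; returns updated pt, or "conflict"/"clash"
apply_action_pt <- function(pt, op, i, j) {
  if (op > 0L) {
    cls <- classify_pair_pt(pt, i, j)
    if (cls != "ok") return(cls)
    pt[i] <- j; pt[j] <- i
  } else {
    if (pt[i] != j) return("conflict")
    pt[i] <- 0L; pt[j] <- 0L
  }
  pt
}

#' Validate a sequence of actions between two structures
#'
#' Applies the actions successively to `A`; the sequence is a valid action
#' chain when every step applies without conflict or clash and the final
#' structure equals `B`.
#'
#' @param A,B Endpoint `rna_structure`s.
#' @param actions An `action_chain` or an m x 3 matrix of `(op, i, j)` rows.
#' @return A list: `ok` (logical); on success `pts`, the `m + 1` pair tables
#'   of the intermediate structures; on failure `step` (first offending
#'   1-based step, or `m + 1` when the end structure is not reached) and
#'   `reason`.
#' @export
validate_chain <- function(A, B, actions) {
  m <- if (is.null(actions)) 0L else nrow(actions)
  pt <- pair_table(A)
  pts <- vector("list", m + 1L)
  pts[[1L]] <- pt
  if (m) {
    for (t in seq_len(m)) {
      pt2 <- apply_action_pt(pt, actions[t, 1L], actions[t, 2L], actions[t, 3L])
      if (is.character(pt2)) {
        return(list(ok = FALSE, step = t, reason = pt2))
      }
      pt <- pt2
      pts[[t + 1L]] <- pt
    }
  }
  if (!identical(pt, pair_table(B))) {
    return(list(ok = FALSE, step = m + 1L, reason = "end structure not reached"))
  }
  list(ok = TRUE, pts = pts)
}

pt_db <- function(pt) {
  ch <- rep(".", length(pt))
  ch[pt > seq_along(pt)] <- "("
  ch[pt != 0L & pt < seq_along(pt)] <- ")"
  paste(ch, collapse = "")
}

# helical runs of consecutive pairs within a pair matrix (not nec. a full
# structure); returns list of matrices, outermost pair first, in 5'->3'
# order of the outer pair
pair_runs <- function(pairs) {
  if (is.null(pairs) || nrow(pairs) == 0L) return(list())
  pairs <- pairs[order(pairs[, 1L]), , drop = FALSE]
  key <- paste(pairs[, 1L], pairs[, 2L])
  runs <- list()
  used <- rep(FALSE, nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    if (used[r]) next
    run <- pairs[r, , drop = FALSE]
    used[r] <- TRUE
    repeat {
      nxt <- paste(run[nrow(run), 1L] + 1L, run[nrow(run), 2L] - 1L)
      hit <- match(nxt, key)
      if (is.na(hit) || used[hit]) break
      run <- rbind(run, pairs[hit, ])
      used[hit] <- TRUE
    }
    runs <- c(runs, list(run))
  }
  runs
}

#' Construct a simple direct pathway
#'
#' The simplest direct pathways delete all pairs of `A - B` and then add all
#' pairs of `B - A`. Deletions and additions are ordered stack-wise — each
#' helical run is degraded or formed contiguously, mimicking successive
#' destruction and formation of stacks — with runs taken in 5'-to-3' order
#' of their outer pair and the within-run direction set by the arguments.
#'
#' @param A,B Endpoint `rna_structure`s over the same length.
#' @param degrade_dir,form_dir `"outermost_first"` or `"innermost_first"`:
#'   direction in which each stack of `A - B` is deleted and each stack of
#'   `B - A` is added.
#' @return A valid `action_chain` of length `bp_distance(A, B)` whose
#'   actions are all direct.
#' @export
simple_pathway <- function(A, B,
                           degrade_dir = c("outermost_first", "innermost_first"),
                           form_dir = c("outermost_first", "innermost_first")) {
  degrade_dir <- match.arg(degrade_dir)
  form_dir <- match.arg(form_dir)
  stopifnot(attr(A, "n") == attr(B, "n"))
  ka <- pair_keys(A); kb <- pair_keys(B)
  dels <- A[!(ka %in% kb), , drop = FALSE]
  adds <- B[!(kb %in% ka), , drop = FALSE]
  rows <- NULL
  for (run in pair_runs(dels)) {
    if (degrade_dir == "innermost_first") run <- run[rev(seq_len(nrow(run))), , drop = FALSE]
    rows <- rbind(rows, cbind(-1L, run))
  }
  for (run in pair_runs(adds)) {
    if (form_dir == "innermost_first") run <- run[rev(seq_len(nrow(run))), , drop = FALSE]
    rows <- rbind(rows, cbind(1L, run))
  }
  chain <- new_chain(rows, A, B)
  v <- validate_chain(A, B, chain)
  if (!v$ok) stop("internal error: simple pathway invalid at step ", v$step)
  chain
}

#' Energy profile, saddle point and barrier of a pathway
#'
#' Evaluates every intermediate structure of a valid action chain and
#' summarizes the pathway: the saddle is the highest-energy structure along
#' the pathway (endpoints included; ties resolved to the earliest step), the
#' barrier is the saddle energy minus the energy of the start structure, and
#' `mean_excess` is the mean energy difference from the start structure over
#' steps `1..m` (the tie-break statistic of the fitness order).
#'
#' @param m An `energy_model`.
#' @param x An `rna_seq`.
#' @param chain A valid `action_chain`.
#' @param strategy Optional label recording which operator produced the
#'   chain (bookkeeping for the evolutionary search).
#' @return An object of class `pathway`: a list with elements `chain`,
#'   `energies` (length `m + 1`), `saddle_index` (0-based step index of the
#'   saddle), `barrier`, `mean_excess`, `m`, `strategy`, `seqno`.
#' @export
energy_profile <- function(m, x, chain, strategy = NA_character_) {
  A <- attr(chain, "A"); B <- attr(chain, "B")
  v <- validate_chain(A, B, chain)
  if (!v$ok) stop("invalid action chain (step ", v$step, ": ", v$reason, ")")
  dbs <- vapply(v$pts, pt_db, character(1))
  e <- evaluate_many(m, x, dbs)
  sad <- which.max(e)                      # first occurrence on ties
  structure(list(
    chain = chain,
    energies = e,
    saddle_index = sad - 1L,
    barrier = e[sad] - e[1L],
    mean_excess = if (length(e) > 1L) mean(e[-1L] - e[1L]) else 0,
    m = nrow(chain),
    strategy = strategy,
    seqno = next_seqno()
  ), class = "pathway")
}

# creation sequence numbers pin down residual fitness ties deterministically
.seqno_env <- new.env(parent = emptyenv())
.seqno_env$k <- 0L
next_seqno <- function() {
  .seqno_env$k <- .seqno_env$k + 1L
  .seqno_env$k
}
reset_seqno <- function() .seqno_env$k <- 0L

#' @export
print.pathway <- function(x, ...) {
  cat(sprintf(
    "Folding pathway: %d actions, barrier %.2f kcal/mol (saddle at step %d, E = %.2f)\n",
    x$m, x$barrier, x$saddle_index, x$energies[x$saddle_index + 1L]))
  invisible(x)
}

fitness_key <- function(p) {
  c(round(p$barrier, 2), round(p$mean_excess, 2), p$m, p$seqno)
}

#' Compare two pathways by fitness
#'
#' Pathways are ordered primarily by energy barrier; ties are broken by the
#' mean energy excess over the start structure, then by chain length
#' (shorter preferred). Energies are compared at 0.01 kcal/mol resolution,
#' the print precision of the evaluators.
#'
#' @param p,q `pathway` objects for the same instance.
#' @return `"p_better"`, `"q_better"` or `"equal"`.
#' @export
compare_fitness <- function(p, q) {
  kp <- fitness_key(p)[1:3]
  kq <- fitness_key(q)[1:3]
  for (k in 1:3) {
    if (kp[k] < kq[k]) return("p_better")
    if (kp[k] > kq[k]) return("q_better")
  }
  "equal"
}

# sort a list of pathways best-first (full key incl. creation order)
sort_pathways <- function(ps) {
  if (length(ps) <= 1L) return(ps)
  keys <- t(vapply(ps, fitness_key, numeric(4)))
  ps[order(keys[, 1L], keys[, 2L], keys[, 3L], keys[, 4L])]
}

# drop duplicate chains (identical action matrices), keeping first occurrence
dedup_pathways <- function(ps) {
  if (length(ps) <= 1L) return(ps)
  sig <- vapply(ps, function(p) paste(as.integer(p$chain), collapse = ","),
                character(1))
  ps[!duplicated(sig)]
}

#' Pathway report table
#'
#' @param record A `pathway`.
#' @return A data frame with one row per structure along the pathway:
#'   `step`, `action` (empty for the start structure), `structure`
#'   (dot-bracket) and `energy` (kcal/mol).
#' @export
pathway_table <- function(record) {
  chain <- record$chain
  v <- validate_chain(attr(chain, "A"), attr(chain, "B"), chain)
  dbs <- vapply(v$pts, pt_db, character(1))
  data.frame(
    step = seq_along(dbs) - 1L,
    action = c("", format(chain)),
    structure = dbs,
    energy = record$energies,
    stringsAsFactors = FALSE
  )
}
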