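# shared fixtures: the 16-nt toy conformational switch and independent
# brute-force oracles used to cross-check the package's fast paths

toy <- function() {
  list(
    x = rna_seq("GGGGAAAACCCCUUUU"),
    A = parse_db("((((....))))...."),
    B = parse_db("....((((....))))")
  )
}

pairs_of <- function(S) unclass(S)[, , drop = FALSE]

union_pairs <- function(A, B) {
  unique(rbind(pairs_of(A), pairs_of(B)))
}

# O(n^3) brute-force stack enumeration: every maximal run of consecutive
# admissible pairs, found by direct scanning of all (i, j, length) triples
brute_stacks <- function(x, min_stack_len = 4L, min_hairpin = 3L) {
  n <- attr(x, "n")
  out <- list()
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j) next
    if (!pair_allowed(x, i, j, min_hairpin)) next
    # (i, j) starts a maximal run iff (i-1, j+1) is not admissible
    prev_ok <- i > 1L && j < n && pair_allowed(x, i - 1L, j + 1L, min_hairpin)
    if (prev_ok) next
    len <- 0L
    while (i + len < j - len &&
           pair_allowed(x, i + len, j - len, min_hairpin)) {
      len <- len + 1L
    }
    if (len >= min_stack_len) {
      out <- c(out, list(cbind(i = i + 0:(len - 1L), j = j - 0:(len - 1L))))
    }
  }
  out
}

stack_signature <- function(st) paste(st[, 1L], st[, 2L], collapse = ";")

# exhaustive minimax barrier over all direct pathways (simple paths in the
# state graph of valid subsets of A union B); independent of the
# union-find sweep in exact_direct_barrier
brute_direct_barrier <- function(model, x, A, B) {
  U <- union_pairs(A, B)
  P <- nrow(U)
  keys <- function(S) paste0("k", paste(sort(pair_keys(S)), collapse = ","))
  Emem <- new.env(parent = emptyenv())
  Ef <- function(S) {
    k <- keys(S)
    v <- Emem[[k]]
    if (is.null(v)) {
      v <- evaluate_energy(model, x, S)
      Emem[[k]] <- v
    }
    v
  }
  target <- keys(B)
  best <- Inf
  rec <- function(S, seen, mx) {
    mx <- max(mx, Ef(S))
    if (mx >= best) return(invisible())
    if (keys(S) == target) {
      best <<- min(best, mx)
      return(invisible())
    }
    for (r in seq_len(P)) {
      i <- U[r, 1L]; j <- U[r, 2L]
      pt <- pair_table(S)
      if (pt[i] == j) {
        pt[i] <- 0L; pt[j] <- 0L
      } else if (classify_pair_pt(pt, i, j) == "ok") {
        pt[i] <- j; pt[j] <- i
      } else next
      S2 <- structure_from_pt(pt)
      k2 <- keys(S2)
      if (k2 %in% seen) next
      rec(S2, c(seen, k2), mx)
    }
  }
  rec(A, keys(A), -Inf)
  best - Ef(A)
}

# internal helpers reached through ::: on purpose: the tests exercise the
# fast pair-table paths directly
classify_pair_pt <- stackpath:::classify_pair_pt
structure_from_pt <- stackpath:::structure_from_pt
pair_keys <- stackpath:::pair_keys

# all permutations of 1..n (tiny n)
combinat_perms <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- combinat_perms(n - 1)
  out <- NULL
  for (k in seq_len(n)) {
    ins <- cbind(sub[, seq_len(k - 1), drop = FALSE], n,
                 sub[, seq_len(n - 1) >= k, drop = FALSE])
    out <- rbind(out, ins)
  }
  out
}

# action multiset signature (order-free)
chain_multiset <- function(chain) {
  m <- unclass(chain)
  sort(paste(m[, 1L], m[, 2L], m[, 3L]))
}

# true multiset difference a \ b (setdiff collapses duplicates)
multiset_diff <- function(a, b) {
  for (e in b) {
    hit <- match(e, a)
    if (!is.na(hit)) a <- a[-hit]
  }
  a
}

small_cfg <- function(seed = 1L, energy = "simple") {
  ea_control(seed = seed, L = 25, l1 = 5, l2 = 3, l3 = 20,
             MAX = 6, gamma = 3, L_min = 1, energy = energy)
}
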