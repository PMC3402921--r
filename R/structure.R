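#' Validated RNA sequence
#'
#' Constructs an RNA sequence object over the alphabet A/C/G/U. Lowercase
#' input is accepted and upper-cased; `T` is normalized to `U` with a warning
#' (common FASTA dialect for transcribed DNA).
#'
#' @param x A single character string of nucleotides.
#' @return An object of class `rna_seq`: a character scalar with attribute
#'   `n` (sequence length).
#' @examples
#' rna_seq("GGGGAAAACCCCUUUU")
#' @export
rna_seq <- function(x) {
  stopifnot(is.character(x), length(x) == 1L, !is.na(x))
  x <- toupper(x)
  if (grepl("T", x, fixed = TRUE)) {
    warning("'T' normalized to 'U' in input sequence")
    x <- gsub("T", "U", x, fixed = TRUE)
  }
  if (!grepl("^[ACGU]+$", x)) {
    bad <- regmatches(x, regexpr("[^ACGU]", x))
    stop("invalid residue '", bad, "' in RNA sequence (alphabet is A/C/G/U)")
  }
  structure(x, n = nchar(x), class = "rna_seq")
}

#' @export
print.rna_seq <- function(x, ...) {
  cat("RNA sequence (", attr(x, "n"), " nt)\n", unclass(x), "\n", sep = "")
  invisible(x)
}

seq_chars <- function(x) strsplit(unclass(x), "", fixed = TRUE)[[1L]]

seq_len_of <- function(x) {
  n <- attr(x, "n")
  if (is.null(n)) nchar(unclass(x)) else n
}

new_structure <- function(pairs, n) {
  if (is.null(pairs) || nrow(pairs) == 0L) {
    pairs <- matrix(integer(0), ncol = 2L)
  } else {
    pairs <- pairs[order(pairs[, 1L]), , drop = FALSE]
  }
  dimnames(pairs) <- list(NULL, c("i", "j"))
  structure(pairs, n = as.integer(n), class = "rna_structure")
}

#' Build a secondary structure from base pairs
#'
#' @param pairs Two-column integer matrix of 1-based pairs `(i, j)` with
#'   `i < j`, or `NULL` for the open structure.
#' @param n Sequence length.
#' @return An `rna_structure`: a two-column matrix of pairs sorted by `i`,
#'   with attribute `n`.
#' @details The pair set must be disjoint (no position in two pairs) and
#'   non-crossing (pseudoknot-free): no two pairs `(i, j)`, `(i', j')` with
#'   `i < i' < j < j'`.
#' @export
rna_structure <- function(pairs, n) {
  n <- as.integer(n)
  stopifnot(n >= 1L)
  if (is.null(pairs)) return(new_structure(NULL, n))
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  if (nrow(pairs) == 0L) return(new_structure(NULL, n))
  if (any(pairs[, 1L] >= pairs[, 2L])) stop("base pairs must have i < j")
  if (any(pairs < 1L) || any(pairs > n)) stop("base pair outside 1..n")
  pos <- c(pairs[, 1L], pairs[, 2L])
  if (anyDuplicated(pos)) stop("position paired more than once")
  S <- new_structure(pairs, n)
  if (has_crossing(S)) stop("crossing base pairs (pseudoknot) not allowed")
  S
}

has_crossing <- function(S) {
  m <- nrow(S)
  if (m < 2L) return(FALSE)
  # pairs sorted by i: crossing iff some later pair starts inside (i,j)
  # and ends outside
  for (a in seq_len(m - 1L)) {
    i <- S[a, 1L]; j <- S[a, 2L]
    b <- (a + 1L):m
    ii <- S[b, 1L]; jj <- S[b, 2L]
    if (any(ii > i & ii < j & jj > j)) return(TRUE)
  }
  FALSE
}

#' Pair-table view of a structure
#'
#' @param S An `rna_structure`.
#' @return Integer vector `pt` of length `n` with `pt[i] = j` when `(i, j)`
#'   or `(j, i)` is paired and `0` when position `i` is unpaired.
#' @export
pair_table <- function(S) {
  pt <- integer(attr(S, "n"))
  if (nrow(S)) {
    pt[S[, 1L]] <- S[, 2L]
    pt[S[, 2L]] <- S[, 1L]
  }
  pt
}

structure_from_pt <- function(pt) {
  i <- which(pt > seq_along(pt))
  new_structure(cbind(i, pt[i]), length(pt))
}

#' Parse dot-bracket notation
#'
#' @param text A dot-bracket string over `.`, `(`, `)`.
#' @return An `rna_structure` whose pairs are the bracket matching.
#' @examples
#' parse_db("((((....))))....")
#' @export
parse_db <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  ch <- strsplit(text, "", fixed = TRUE)[[1L]]
  bad <- which(!ch %in% c(".", "(", ")"))
  if (length(bad)) {
    stop("illegal character '", ch[bad[1L]], "' at position ", bad[1L],
         " in dot-bracket string")
  }
  open <- integer(0)
  pairs <- matrix(integer(0), ncol = 2L)
  for (k in seq_along(ch)) {
    if (ch[k] == "(") {
      open <- c(open, k)
    } else if (ch[k] == ")") {
      if (!length(open)) stop("unbalanced ')' at position ", k)
      pairs <- rbind(pairs, c(open[length(open)], k))
      open <- open[-length(open)]
    }
  }
  if (length(open)) stop("unbalanced '(' at position ", open[1L])
  new_structure(pairs, length(ch))
}

#' Render a structure in dot-bracket notation
#'
#' @param S An `rna_structure`.
#' @return The dot-bracket string of length `n`.
#' @export
db_string <- function(S) {
  n <- attr(S, "n")
  ch <- rep(".", n)
  if (nrow(S)) {
    if (any(S < 1L) || any(S > n)) stop("base pair outside 1..n")
    ch[S[, 1L]] <- "("
    ch[S[, 2L]] <- ")"
  }
  paste(ch, collapse = "")
}

#' @export
print.rna_structure <- function(x, ...) {
  cat("RNA secondary structure (", nrow(x), " pairs, n = ", attr(x, "n"),
      ")\n", db_string(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.rna_structure <- function(x, ...) db_string(x)

#' Is a base pair admissible for a sequence?
#'
#' Admits the canonical pairings A-U and G-C and the wobble pairing G-U,
#' subject to a minimum hairpin loop of `min_hairpin` unpaired bases
#' (`j - i - 1 >= min_hairpin`).
#'
#' @param x An `rna_seq`.
#' @param i,j 1-based positions with `i < j`.
#' @param min_hairpin Minimum loop size enclosed by a pair (default 3).
#' @return `TRUE` or `FALSE`.
#' @export
pair_allowed <- function(x, i, j, min_hairpin = 3L) {
  stopifnot(i >= 1L, j <= seq_len_of(x), i < j)
  if (j - i - 1L < min_hairpin) return(FALSE)
  ch <- seq_chars(x)
  duo <- paste0(ch[i], ch[j])
  duo %in% c("AU", "UA", "GC", "CG", "GU", "UG")
}

#' Classify a candidate base pair against a structure
#'
#' A pair *conflicts* with `S` if either of its positions is already paired;
#' it *clashes* if some pair of `S` crosses it (would create a pseudoknot);
#' otherwise it is *ok* and can be added.
#'
#' @param S An `rna_structure`.
#' @param i,j Candidate pair positions, `i < j`.
#' @return One of `"ok"`, `"conflict"`, `"clash"`.
#' @export
classify_pair <- function(S, i, j) {
  pt <- pair_table(S)
  classify_pair_pt(pt, i, j)
}

# pair-table fast path used throughout the search
classify_pair_pt <- function(pt, i, j) {
  if (pt[i] != 0L || pt[j] != 0L) return("conflict")
  if (j - i > 1L) {
    inside <- pt[(i + 1L):(j - 1L)]
    if (any(inside != 0L & (inside < i | inside > j))) return("clash")
  }
  "ok"
}

#' Base-pair distance between two structures
#'
#' The number of pairs in `A` not in `B` plus the number in `B` not in `A`.
#'
#' @param A,B `rna_structure` objects over the same sequence length.
#' @return Non-negative integer count.
#' @export
bp_distance <- function(A, B) {
  stopifnot(attr(A, "n") == attr(B, "n"))
  ka <- pair_keys(A); kb <- pair_keys(B)
  sum(!(ka %in% kb)) + sum(!(kb %in% ka))
}

pair_keys <- function(S) {
  if (!nrow(S)) return(integer(0))
  S[, 1L] * (attr(S, "n") + 1L) + S[, 2L]
}

#' Enumerate helical stacks of a sequence
#'
#' Scans every anti-diagonal of the complementarity matrix for maximal runs
#' of consecutive admissible pairs `(i, j), (i+1, j-1), ...` and returns the
#' runs of at least `min_stack_len` pairs. Only maximal runs are reported:
#' sub-stacks add no reachable moves to the stack-guided operators while
#' inflating the candidate set.
#'
#' @param x An `rna_seq`.
#' @param min_stack_len Minimum number of consecutive pairs (default 4).
#' @param min_hairpin Minimum hairpin loop size (default 3).
#' @return A list of stacks, each a two-column integer matrix of pairs from
#'   outermost to innermost.
#' @examples
#' enumerate_stacks(rna_seq("GGGGAAAACCCCUUUU"))
#' @export
enumerate_stacks <- function(x, min_stack_len = 4L, min_hairpin = 3L) {
  stopifnot(min_stack_len >= 1L)
  n <- seq_len_of(x)
  out <- list()
  for (d in 3L:(2L * n - 1L)) {      # d = i + j
    i_min <- max(1L, d - n)
    i_max <- (d - 1L) %/% 2L
    if (i_max < i_min) next
    run <- NULL
    for (i in i_min:i_max) {
      j <- d - i
      ok <- j - i - 1L >= min_hairpin && pair_allowed(x, i, j, min_hairpin)
      if (ok) {
        run <- rbind(run, c(i, j))
      } else {
        if (!is.null(run) && nrow(run) >= min_stack_len) out <- c(out, list(run))
        run <- NULL
      }
    }
    if (!is.null(run) && nrow(run) >= min_stack_len) out <- c(out, list(run))
  }
  lapply(out, function(m) {
    dimnames(m) <- list(NULL, c("i", "j"))
    m
  })
}

#' Is a stack compatible with a structure?
#'
#' A stack is compatible with `S` when every member pair is either already
#' in `S` or can be added without conflict or clash (members are added
#' innermost-out while testing, so a fully addable stack is compatible).
#'
#' @param stack Two-column matrix of stack pairs (outermost first).
#' @param S An `rna_structure`.
#' @return `TRUE` (compatible) or `FALSE` (incompatible).
#' @export
stack_compatible <- function(stack, S) {
  pt <- pair_table(S)
  for (r in rev(seq_len(nrow(stack)))) {   # innermost first
    i <- stack[r, 1L]; j <- stack[r, 2L]
    if (pt[i] == j) next                    # already present
    if (classify_pair_pt(pt, i, j) != "ok") return(FALSE)
    pt[i] <- j; pt[j] <- i
  }
  TRUE
}
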