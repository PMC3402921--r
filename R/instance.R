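#' Refolding instance
#'
#' @param x Sequence (character or `rna_seq`).
#' @param A,B Start and end structures (dot-bracket or `rna_structure`).
#' @param label Instance identifier.
#' @return A list of class `rna_instance` with elements `sequence`, `A`,
#'   `B`, `label`.
#' @export
rna_instance <- function(x, A, B, label = "instance") {
  if (!inherits(x, "rna_seq")) x <- rna_seq(x)
  if (!inherits(A, "rna_structure")) A <- parse_db(A)
  if (!inherits(B, "rna_structure")) B <- parse_db(B)
  n <- seq_len_of(x)
  if (attr(A, "n") != n || attr(B, "n") != n) {
    stop("sequence and structures must have equal length (", n, ")")
  }
  structure(list(sequence = x, A = A, B = B, label = label),
            class = "rna_instance")
}

#' @export
print.rna_instance <- function(x, ...) {
  cat("Refolding instance '", x$label, "' (", seq_len_of(x$sequence),
      " nt)\n", sep = "")
  cat(unclass(x$sequence), "\n", db_string(x$A), "\n", db_string(x$B), "\n",
      sep = "")
  invisible(x)
}

#' Read a refolding instance from disk
#'
#' Two layouts are supported. A single plain-text file with three
#' non-empty lines — sequence, start structure, end structure — or a FASTA
#' file for the sequence plus a structures file with two dot-bracket
#' lines. Only the first FASTA record is used (a warning is raised for
#' multi-record input); `T` is normalized to `U` with a warning.
#'
#' @param path Path to the 3-line instance file, or to a FASTA file when
#'   `structures` is given.
#' @param structures Optional path to a 2-line dot-bracket file.
#' @param label Instance label; defaults to the file name.
#' @return An `rna_instance`.
#' @export
read_instance <- function(path, structures = NULL,
                          label = sub("\\.[^.]*$", "", basename(path))) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(structures)) {
    lines <- trimws(readLines(path, warn = FALSE))
    lines <- lines[nzchar(lines)]
    if (length(lines) && startsWith(lines[1L], ">")) {
      stop("FASTA input requires a separate structures file ",
           "(read_instance(path, structures))")
    }
    if (length(lines) < 3L) stop("instance file must have 3 non-empty lines")
    return(rna_instance(lines[1L], lines[2L], lines[3L], label))
  }
  seq <- read_fasta_first(path)
  sl <- trimws(readLines(structures, warn = FALSE))
  sl <- sl[nzchar(sl)]
  if (length(sl) < 2L) stop("structures file must have 2 non-empty lines")
  rna_instance(seq, sl[1L], sl[2L], label)
}

read_fasta_first <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty FASTA file: ", path)
  hdr <- which(startsWith(lines, ">"))
  if (!length(hdr)) stop("not a FASTA file (no '>' header): ", path)
  if (length(hdr) > 1L) {
    warning("multi-record FASTA: using first record only")
  }
  to <- if (length(hdr) > 1L) hdr[2L] - 1L else length(lines)
  paste(lines[(hdr[1L] + 1L):to], collapse = "")
}

#' Write pathway reports
#'
#' Writes three files into `out_dir`: `pathway.txt`, a plain-text table
#' with one row per structure (step, action, dot-bracket, energy);
#' `report.json`, a machine-readable run report (instance, configuration
#' including the seed, barrier, saddle index, full energy profile, action
#' list, and per-generation statistics when a trace is given); and
#' `trace.csv` with the per-generation search statistics. No timestamps
#' are written, so identical runs produce byte-identical reports.
#'
#' @param record A `pathway`.
#' @param instance An `rna_instance`.
#' @param cfg The `ea_control` used (or `NULL`).
#' @param trace Per-generation data frame (or `NULL`).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_reports <- function(record, instance, cfg = NULL, trace = NULL,
                          out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tbl <- pathway_table(record)
  txt <- file.path(out_dir, "pathway.txt")
  widths <- c(4, max(nchar(tbl$action), 10), nchar(tbl$structure[1L]), 8)
  hdr <- sprintf("%-*s %-*s %-*s %*s", widths[1], "step", widths[2], "action",
                 widths[3], "structure", widths[4], "energy")
  rows <- sprintf("%-*d %-*s %-*s %*.2f", widths[1], tbl$step,
                  widths[2], tbl$action, widths[3], tbl$structure,
                  widths[4], tbl$energy)
  writeLines(c(hdr, rows), txt)

  chain <- record$chain
  actions <- if (nrow(chain)) {
    lapply(seq_len(nrow(chain)), function(t) list(
      kind = if (chain[t, 1L] > 0L) "add" else "del",
      i = chain[t, 2L], j = chain[t, 3L]))
  } else list()
  report <- list(
    instance = list(label = instance$label,
                    sequence = unclass(instance$sequence),
                    A = db_string(instance$A), B = db_string(instance$B)),
    config = if (is.null(cfg)) NULL else unclass(cfg),
    barrier = record$barrier,
    saddle_index = record$saddle_index,
    saddle_energy = record$energies[record$saddle_index + 1L],
    mean_excess = record$mean_excess,
    n_actions = record$m,
    profile = record$energies,
    actions = actions,
    generations = if (is.null(trace)) NULL else trace
  )
  jsn <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, jsn, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  csv <- file.path(out_dir, "trace.csv")
  if (!is.null(trace)) {
    utils::write.csv(trace, csv, row.names = FALSE)
  } else {
    csv <- NULL
  }
  invisible(c(txt, jsn, csv))
}

#' Generate a synthetic refolding instance
#'
#' Builds a random sequence with planted helices (a random helix strand,
#' a 3-nt loop, and its reverse complement, repeated while space permits,
#' padded with random nucleotides), enumerates its stack set, and draws
#' the two endpoint structures as unions of mutually compatible stacks.
#' Generation retries until the endpoints differ (and, optionally, until
#' the pair union is small enough for the exact direct-pathway oracle).
#' Deterministic for a given seed; the caller's RNG state is restored on
#' exit.
#'
#' @param n Sequence length (at least 12).
#' @param k_stacks Stacks per endpoint structure (default 1).
#' @param seed Integer seed.
#' @param max_union Optional cap on the size of the pair union of the two
#'   endpoints (for oracle-checkable instances).
#' @param min_stack_len Minimum stack length (default 4).
#' @return An `rna_instance`.
#' @export
random_instance <- function(n, k_stacks = 1L, seed = 1L, max_union = NULL,
                            min_stack_len = 4L) {
  stopifnot(n >= 12L)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  nts <- c("A", "C", "G", "U")
  rc <- c(A = "U", C = "G", G = "C", U = "A")
  for (attempt in seq_len(500L)) {
    # plant helices: strand + loop + reverse complement, then random fill
    ch <- character(0)
    while (length(ch) + 12L <= n) {
      hl <- sample(4:5, 1L)
      if (length(ch) + 2L * hl + 3L > n) break
      h <- sample(nts, hl, replace = TRUE, prob = c(.2, .3, .3, .2))
      ch <- c(ch, h, sample(nts, 3L, replace = TRUE),
              rev(unname(rc[h])), sample(nts, sample(0:2, 1L), replace = TRUE))
    }
    if (length(ch) < n) ch <- c(ch, sample(nts, n - length(ch), replace = TRUE))
    x <- rna_seq(paste(ch[seq_len(n)], collapse = ""))
    sta <- enumerate_stacks(x, min_stack_len)
    if (length(sta) < 2L) next
    for (draw in seq_len(20L)) {
      A <- stack_union(sta, k_stacks, n)
      B <- stack_union(sta, k_stacks, n)
      if (is.null(A) || is.null(B)) next
      if (bp_distance(A, B) < 1L) next
      if (!is.null(max_union)) {
        u <- nrow(unique(rbind(unclass(A)[, , drop = FALSE],
                               unclass(B)[, , drop = FALSE])))
        if (u > max_union) next
      }
      return(rna_instance(x, A, B, label = sprintf("synthetic_n%d_s%d", n, seed)))
    }
  }
  stop("failed to generate an instance for n = ", n, ", k_stacks = ",
       k_stacks, ", seed = ", seed)
}

# union of up to k mutually compatible stacks drawn at random
stack_union <- function(sta, k, n) {
  ord <- sample.int(length(sta))
  S <- rna_structure(NULL, n)
  got <- 0L
  for (idx in ord) {
    st <- sta[[idx]]
    if (stack_compatible(st, S)) {
      pt <- pair_table(S)
      add <- st[pt[st[, 1L]] != st[, 2L], , drop = FALSE]
      if (nrow(add) == 0L) next
      S <- rna_structure(rbind(unclass(S)[, , drop = FALSE], add), n)
      got <- got + 1L
      if (got >= k) break
    }
  }
  if (got == 0L) NULL else S
}
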