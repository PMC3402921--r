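#' Fit a low-barrier refolding pathway between two RNA structures
#'
#' The main entry point. Given one RNA sequence and two pseudoknot-free
#' secondary structures `A` (start) and `B` (end), searches for a folding
#' pathway from `A` to `B` with a low energy barrier — the difference
#' between the highest-energy structure along the pathway (the saddle
#' point) and the start structure. The search is an evolutionary algorithm
#' over action chains (ordered base-pair additions and deletions) whose
#' mutation operators are guided by the formation and destruction of
#' helical stacks rather than by greedy energy descent; candidate pathways
#' are selected on their barrier.
#'
#' @param x RNA sequence (character or `rna_seq`).
#' @param A,B Start and end structures (dot-bracket strings or
#'   `rna_structure`s) of the same length as `x`.
#' @param control An [ea_control()] with search and energy settings.
#' @param runs Number of independent seeded runs; the best pathway over
#'   all runs is reported (run `r` uses seed `seed + r - 1`).
#' @return An object of class `stackpath_fit` with components `best` (the
#'   best `pathway`), `trace` (per-generation statistics of the winning
#'   run), `runs` (barrier per run), `E_A`, `E_B`, `instance`, `control`
#'   and `call`.
#' @examples
#' fit <- stackpath("GGGGAAAACCCCUUUU",
#'                  "((((....))))....",
#'                  "....((((....))))",
#'                  control = ea_control(seed = 1, L = 20, MAX = 3))
#' fit
#' @seealso [run_ea()] for a single run, [exact_direct_barrier()] for the
#'   exact optimum over direct pathways on small instances.
#' @export
stackpath <- function(x, A, B, control = ea_control(), runs = 1L) {
  cl <- match.call()
  if (!inherits(x, "rna_seq")) x <- rna_seq(x)
  if (!inherits(A, "rna_structure")) A <- parse_db(A)
  if (!inherits(B, "rna_structure")) B <- parse_db(B)
  base_seed <- control$seed
  results <- vector("list", runs)
  for (r in seq_len(runs)) {
    cfg <- control
    if (!is.null(base_seed)) cfg$seed <- base_seed + r - 1L
    results[[r]] <- run_ea(x, A, B, cfg)
  }
  barriers <- vapply(results, function(z) z$best$barrier, numeric(1))
  best_run <- which.min(round(barriers, 2))
  res <- results[[best_run]]
  structure(list(
    best = res$best,
    trace = res$trace,
    runs = data.frame(run = seq_len(runs),
                      seed = if (is.null(base_seed)) NA_integer_ else
                        base_seed + seq_len(runs) - 1L,
                      barrier = barriers),
    generations = res$generations,
    E_A = res$E_A, E_B = res$E_B,
    instance = list(sequence = unclass(x), A = db_string(A), B = db_string(B)),
    control = control, call = cl
  ), class = "stackpath_fit")
}

#' @export
print.stackpath_fit <- function(x, ...) {
  cat("Stack-guided refolding pathway search\n")
  cat("Sequence (", nchar(x$instance$sequence), " nt): ",
      x$instance$sequence, "\n", sep = "")
  cat("A: ", x$instance$A, "  E =", sprintf("%.2f", x$E_A), "kcal/mol\n")
  cat("B: ", x$instance$B, "  E =", sprintf("%.2f", x$E_B), "kcal/mol\n")
  cat(sprintf(
    "Best pathway: %d actions, barrier %.2f kcal/mol (saddle %.2f at step %d)\n",
    x$best$m, x$best$barrier,
    x$best$energies[x$best$saddle_index + 1L], x$best$saddle_index))
  cat("Energy model:", x$control$energy,
      if (x$control$energy == "turner")
        paste0("(", x$control$parameter_set %||% "turner1999", ", d1)"),
      "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
summary.stackpath_fit <- function(object, ...) {
  out <- list(fit = object, table = pathway_table(object$best))
  class(out) <- "summary.stackpath_fit"
  out
}

#' @export
print.summary.stackpath_fit <- function(x, ...) {
  print(x$fit)
  cat("\nPathway:\n")
  tbl <- x$table
  tbl$energy <- sprintf("%7.2f", tbl$energy)
  print(tbl, row.names = FALSE)
  if (nrow(x$fit$trace)) {
    cat("\nBarrier by generation:",
        paste(sprintf("%.2f", x$fit$trace$barrier), collapse = " "), "\n")
  }
  invisible(x)
}

#' @export
plot.stackpath_fit <- function(x, which = c("profile", "trace"), ...) {
  which <- match.arg(which)
  if (which == "profile") {
    e <- x$best$energies
    plot(seq_along(e) - 1L, e, type = "b", pch = 19,
         xlab = "step", ylab = "free energy (kcal/mol)",
         main = "Energy profile of best pathway", ...)
    points(x$best$saddle_index, e[x$best$saddle_index + 1L],
           col = 2, pch = 19, cex = 1.4)
    abline(h = e[1L], lty = 3)
  } else {
    tr <- x$trace
    plot(tr$generation, tr$barrier, type = "b", pch = 19,
         xlab = "generation", ylab = "best barrier (kcal/mol)",
         main = "Search progress", ...)
  }
  invisible(x)
}

#' @export
as.data.frame.stackpath_fit <- function(x, ...) pathway_table(x$best)
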