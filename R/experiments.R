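# Reproducible experiment grids: amplification-ratio heatmaps, the
# interpolation-accuracy check, and implied-scale-of-fitness curves.

# Resolve a family spec (list(kind =, n =, m =, blades =, epsilon =))
# or a ready-made graph into a weighted_digraph.
resolve_family <- function(spec) {
  if (inherits(spec, "weighted_digraph")) return(spec)
  do.call(make_family, spec)
}

#' Amplification-ratio grid over (r, delta)
#'
#' For each family and each grid cell `(r, delta)` computes the exact
#' fixation probability (closed form / lumped chain / full solve as
#' appropriate) and its ratio to the well-mixed baseline
#' `rho^delta(K_N, r)`. Ratios above 1 mark amplification, below 1
#' suppression. The default grids are `r in {1, 1.025, ..., 3}` and
#' `delta in {0, 0.025, ..., 1}`.
#'
#' @param families A list of family specs, each either a
#'   [weighted_digraph()] or a list of [make_family()] arguments, e.g.
#'   `list(list(kind = "star", n = 10))`.
#' @param r_grid,delta_grid Increasing numeric grids.
#' @param baseline Baseline kind for `0 < delta < 1`; see
#'   [classify_amplifier()].
#' @return A data frame with columns `family`, `n`, `r`, `delta`, `rho`,
#'   `baseline`, `ratio`. Deterministic (exact routes only).
#' @export
run_delta_grid <- function(families,
                           r_grid = seq(1, 3, by = 0.025),
                           delta_grid = seq(0, 1, by = 0.025),
                           baseline = c("interpolation", "exact-complete")) {
  baseline <- match.arg(baseline)
  stopifnot(length(r_grid) > 0, length(delta_grid) > 0,
            !is.unsorted(r_grid), !is.unsorted(delta_grid))
  out <- list()
  for (spec in families) {
    g <- resolve_family(spec)
    cells <- expand.grid(delta = delta_grid, r = r_grid)
    rho <- mapply(function(r, d) rho_exact_route(g, r, d)$rho,
                  cells$r, cells$delta)
    base <- mapply(function(r, d) baseline_rho(g$n, r, d, baseline)$value,
                   cells$r, cells$delta)
    out[[length(out) + 1]] <- data.frame(
      family = g$family, n = g$n, r = cells$r, delta = cells$delta,
      rho = rho, baseline = base, ratio = rho / base)
  }
  do.call(rbind, out)
}

#' Accuracy of the linear-interpolation baseline
#'
#' Compares the exact complete-graph fixation probability under delta-dB
#' updating ([rho_delta_complete_exact()]) with the linear interpolation
#' [rho_hat_interpolation()] over a grid of `(N, r, delta)`. The
#' interpolation is exact at `N = 2` and at the endpoints `delta = 0, 1`,
#' and agrees within about 1% (typically 0.1%) elsewhere.
#'
#' @param n_list Population sizes.
#' @param r_list Fitness values.
#' @param delta_grid Values of `delta` in `[0, 1]`.
#' @return A data frame `(n, r, delta, rho_exact, rho_hat, ratio)` with
#'   attribute `max_abs_dev` = `max |ratio - 1|`.
#' @examples
#' chk <- run_interpolation_check(c(2, 5), c(2), seq(0, 1, 0.25))
#' attr(chk, "max_abs_dev")
#' @export
run_interpolation_check <- function(n_list = c(2, 5, 10, 20),
                                    r_list = c(1.25, 2, 4),
                                    delta_grid = seq(0, 1, by = 0.1)) {
  cells <- expand.grid(delta = delta_grid, r = r_list, n = n_list)
  exact <- mapply(rho_delta_complete_exact, cells$n, cells$r, cells$delta)
  hat <- mapply(rho_hat_interpolation, cells$n, cells$r, cells$delta)
  out <- data.frame(n = cells$n, r = cells$r, delta = cells$delta,
                    rho_exact = exact, rho_hat = hat, ratio = hat / exact)
  attr(out, "max_abs_dev") <- max(abs(out$ratio - 1))
  out
}

#' Implied-scale-of-fitness curves for graph families
#'
#' Computes the finite-`N` implied scale of fitness
#' `isf(r) = 1 / (1 - rho)` for each family over a fitness grid, under
#' pure Bd or pure dB updating. Large `N` (e.g. 400) emulates the
#' large-population limit: complete graphs give `isf = r`; Bd Star and
#' Bipartite graphs approach quadratic curves; under dB no family
#' exceeds `r + 1`.
#'
#' @inheritParams run_delta_grid
#' @param r_grid Fitness grid (`r >= 1`).
#' @param update `"Bd"` or `"dB"`.
#' @return A data frame `(family, n, r, rho, isf)`.
#' @export
run_isf_curves <- function(families, r_grid = seq(1, 3, by = 0.25),
                           update = c("Bd", "dB")) {
  update <- match.arg(update)
  delta <- if (update == "Bd") 0 else 1
  out <- list()
  for (spec in families) {
    g <- resolve_family(spec)
    rho <- vapply(r_grid, function(r) rho_exact_route(g, r, delta)$rho,
                  numeric(1))
    out[[length(out) + 1]] <- data.frame(
      family = g$family, n = g$n, r = r_grid, rho = rho,
      isf = implied_scale_of_fitness(rho))
  }
  do.call(rbind, out)
}

#' Write or read an experiment table as annotated TSV
#'
#' Tables are written as plain TSV preceded by `#`-prefixed metadata
#' lines (tool version plus any caller-supplied key-value metadata), so
#' the numerical artifacts are self-describing and round-trip exactly.
#'
#' @param df A data frame (numeric columns are printed to full
#'   precision).
#' @param path Output path.
#' @param meta Named character vector or list of extra metadata lines.
#' @return `write_results_tsv()` returns `path` invisibly;
#'   `read_results_tsv()` returns the data frame (metadata in attribute
#'   `meta`).
#' @export
write_results_tsv <- function(df, path, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  ver <- as.character(utils::packageVersion("moranamp"))
  writeLines(sprintf("# moranamp %s", ver), con)
  if (!is.null(meta))
    writeLines(sprintf("# %s: %s", names(meta), unlist(meta)), con)
  writeLines(paste(names(df), collapse = "\t"), con)
  fmt <- vapply(df, function(col) {
    if (is.numeric(col)) sprintf("%.17g", col)
    else as.character(col)
  }, character(nrow(df)))
  writeLines(apply(matrix(fmt, nrow = nrow(df)), 1, paste, collapse = "\t"),
             con)
  invisible(path)
}

#' @rdname write_results_tsv
#' @export
read_results_tsv <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.delim(text = paste(body, collapse = "\n"),
                          stringsAsFactors = FALSE)
  attr(df, "meta") <- sub("^#\\s*", "", meta)
  df
}
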