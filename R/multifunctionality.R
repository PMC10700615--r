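# Standardization of function values and multifunctionality metrics: the
# averaged index, the effective number of functions N^q (a Hill number over
# the function profile), and effective multifunctionality N^q * A.

#' Standardize function columns across plots
#'
#' Columnwise standardization of the function matrix: `percent_of_max` maps
#' each value to 100 * x / max(column) (used for the averaged index);
#' `unit_interval` maps to x / max(column), so 0 means no function and 1 the
#' maximum observed level (used for the Hill-number metrics). Standardization
#' is invariant to positive rescaling of a raw column. An all-zero column is
#' set to 0 with a warning. Columns with negative values (possible for net
#' N immobilization or benefit transforms) keep their sign here; the
#' Hill-number profile shifts them later (see [multifun_profile()]).
#'
#' @param fm Function matrix from [build_function_matrix()] or
#'   [generate_experiment()] (tibble with `plot_id`, `treatment` and numeric
#'   function columns).
#' @param mode `"percent_of_max"` or `"unit_interval"`.
#' @param columns Columns to standardize; defaults to every numeric column
#'   present (the 12 functions plus any biomass components).
#' @return Tibble of the same shape with standardized columns; the mode is
#'   recorded in attribute `"mode"`.
#' @export
#' @examples
#' fm <- tibble::tibble(
#'   plot_id = 1:3, treatment = "a",
#'   primary_production = c(1, 2, 4)
#' )
#' standardize_functions(fm, "percent_of_max")$primary_production # 25 50 100
standardize_functions <- function(fm,
                                  mode = c("percent_of_max", "unit_interval"),
                                  columns = NULL) {
  mode <- match.arg(mode)
  if (nrow(fm) < 1) stop("need at least one plot", call. = FALSE)
  if (is.null(columns)) {
    columns <- setdiff(
      names(fm)[vapply(fm, is.numeric, logical(1))],
      c("plot_id", "replicate")
    )
  }
  scale_to <- if (mode == "percent_of_max") 100 else 1
  out <- fm
  for (col in columns) {
    mx <- max(fm[[col]])
    if (mx == 0 && all(fm[[col]] == 0)) {
      warning("column `", col, "` is all zero; standardized to 0")
      out[[col]] <- 0
    } else if (mx <= 0) {
      stop("column `", col, "` has a non-positive maximum; cannot standardize",
        call. = FALSE
      )
    } else {
      out[[col]] <- scale_to * fm[[col]] / mx
    }
  }
  attr(out, "mode") <- mode
  attr(out, "columns") <- columns
  out
}

#' Averaged multifunctionality index
#'
#' The unweighted arithmetic mean of the standardized function values of each
#' plot, over all twelve functions or over the aboveground / belowground
#' subset (see [function_partition()]; the partition uses the biomass
#' component columns in place of total primary production).
#'
#' @param std Output of [standardize_functions()].
#' @param subset `"all"`, `"above"`, or `"below"`.
#' @return Tibble `plot_id`, `treatment`, `avg_index`.
#' @export
average_index <- function(std, subset = c("all", "above", "below")) {
  subset <- match.arg(subset)
  cols <- switch(subset,
    all = marsh_functions(),
    above = function_partition()$above,
    below = function_partition()$below
  )
  missing <- setdiff(cols, names(std))
  if (length(missing) > 0) {
    stop(
      "standardized matrix lacks column(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  std |>
    dplyr::mutate(avg_index = rowMeans(dplyr::pick(dplyr::all_of(cols)))) |>
    dplyr::select("plot_id", "treatment", "avg_index")
}

#' Effective number of functions (Hill number of a function profile)
#'
#' For a plot's standardized function values F_i >= 0, the relative
#' contributions are p_i = F_i / sum(F). The effective number of functions of
#' order q is `N^q = (sum p_i^q)^(1/(1-q))` for q != 1 and its limit
#' `N^1 = exp(-sum p_i log p_i)` (with 0 log 0 = 0) at q = 1. `N^0` counts
#' the functions with a positive value; for a profile of k equally provided
#' functions `N^q = k` at every q, and N^q is non-increasing in q.
#'
#' @param f Non-negative standardized function values of one plot; `sum(f)`
#'   must be positive.
#' @param q Order(s), q >= 0 (vectorised).
#' @return Effective number of functions for each `q`.
#' @export
#' @examples
#' effective_number(rep(0.5, 12), q = 3) # 12
#' effective_number(c(0.8, 0.2), q = 1)
effective_number <- function(f, q) {
  if (any(f < 0)) stop("function values must be non-negative", call. = FALSE)
  if (sum(f) <= 0) {
    stop("all function values are zero; effective number undefined",
      call. = FALSE
    )
  }
  if (any(q < 0)) stop("`q` must be >= 0", call. = FALSE)
  p <- f[f > 0] / sum(f) # zero-valued functions contribute p_i = 0
  vapply(q, function(qi) {
    if (abs(qi - 1) < 1e-12) {
      exp(-sum(p * log(p)))
    } else {
      sum(p^qi)^(1 / (1 - qi))
    }
  }, numeric(1))
}

#' Effective multifunctionality
#'
#' Cumulative system performance of order q: the effective number of functions
#' multiplied by the arithmetic mean level A of the standardized functions,
#' `qM_ef = N^q * A`.
#'
#' @inheritParams effective_number
#' @return `N^q * mean(f)` for each `q`.
#' @export
effective_multifunctionality <- function(f, q) {
  effective_number(f, q) * mean(f)
}

#' Per-plot multifunctionality profile over a grid of orders
#'
#' Computes, for every plot, the averaged index A, the effective number of
#' functions N^q, and effective multifunctionality N^q * A on a grid of
#' orders. If any function column contains negative values (the relative-
#' proportion formula requires F_i >= 0) the column is shifted so its minimum
#' is 0, with a warning.
#'
#' @param std Output of `standardize_functions(fm, "unit_interval")`.
#' @param q_grid Orders, default `0:5`.
#' @param columns Function columns; default the twelve in [marsh_functions()].
#' @return Tidy tibble `plot_id, treatment, q, n_eff, avg_index, m_ef`.
#' @export
multifun_profile <- function(std, q_grid = 0:5,
                             columns = marsh_functions()) {
  mat <- std[, columns, drop = FALSE]
  neg <- vapply(mat, function(x) any(x < 0), logical(1))
  if (any(neg)) {
    warning(
      "shifting column(s) with negative values to a minimum of 0: ",
      paste(columns[neg], collapse = ", ")
    )
    for (col in columns[neg]) mat[[col]] <- mat[[col]] - min(mat[[col]])
  }
  rows <- lapply(seq_len(nrow(std)), function(i) {
    f <- as.numeric(mat[i, ])
    tibble::tibble(
      plot_id = std$plot_id[i],
      treatment = std$treatment[i],
      q = q_grid,
      n_eff = effective_number(f, q_grid),
      avg_index = mean(f),
      m_ef = n_eff * mean(f)
    )
  })
  dplyr::bind_rows(rows)
}
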