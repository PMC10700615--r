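# shared fixtures, built in code

# small function matrix with hand-chosen values (3 plots, all 12 functions)
tiny_fm <- function() {
  fns <- marsh_functions()
  values <- matrix(
    rep(c(1, 2, 4), each = length(fns)),
    nrow = 3, byrow = TRUE, dimnames = list(NULL, fns)
  )
  dplyr::bind_cols(
    tibble::tibble(plot_id = paste0("p", 1:3), treatment = c("a", "a", "b")),
    tibble::as_tibble(values)
  )
}

# fast experiment: function matrix only
quick_functions <- function(config) {
  generate_experiment(config, include = "functions")$functions
}

# small crab series with known arm means (one month)
manual_series <- function(excl_counts, ctrl_counts, year = 2021, month = 5) {
  dplyr::bind_rows(
    tibble::tibble(
      plot_id = paste0("PE_", seq_along(excl_counts)),
      treatment = "planting_exclusion",
      year = year, month = month, count = excl_counts
    ),
    tibble::tibble(
      plot_id = paste0("PC_", seq_along(ctrl_counts)),
      treatment = "planting_control",
      year = year, month = month, count = ctrl_counts
    )
  )
}
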