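#' Tarsometatarsus aspect ratio
#'
#' Total proximodistal length divided by mediolateral width at the midpoint.
#' Conventionally reported as a width:length string, e.g. an aspect ratio of
#' 11.1 prints as `"1:11"`.
#'
#' @param length,width Positive lengths in the same units (mm).
#' @return `aspect_ratio()` returns length/width (dimensionless);
#'   `format_aspect_ratio()` renders `"1:round(x)"`.
#' @examples
#' aspect_ratio(82.3, 7.4)          # 11.12
#' format_aspect_ratio(aspect_ratio(82.3, 7.4))  # "1:11"
#' @export
aspect_ratio <- function(length, width) {
  if (any(length <= 0) || any(width <= 0)) {
    abort("`length` and `width` must be positive.")
  }
  length / width
}

#' @rdname aspect_ratio
#' @param x An aspect ratio value.
#' @export
format_aspect_ratio <- function(x) sprintf("1:%d", round(x))

#' Proportional position of the m. tibialis cranialis tubercle
#'
#' Distance from the proximal margin of the tarsometatarsus to the tubercle
#' center, as a fraction of total tarsometatarsus length. This fraction is
#' the relative inlever of the dorsiflexion lever.
#'
#' @param tubercle_distance Proximal margin to tubercle center (mm), > 0.
#' @param tmt_length Total tarsometatarsus length (mm), > `tubercle_distance`.
#' @return Fraction in (0, 1).
#' @examples
#' tubercle_proportion(21.3, 62.6)   # 0.34
#' @export
tubercle_proportion <- function(tubercle_distance, tmt_length) {
  if (any(tubercle_distance <= 0)) abort("`tubercle_distance` must be positive.")
  if (any(tubercle_distance >= tmt_length)) {
    abort("`tubercle_distance` must be strictly less than `tmt_length`.")
  }
  tubercle_distance / tmt_length
}

#' Summarize a specimen series into a representative individual
#'
#' Averages per-specimen skeletal metrics (arithmetic mean, sample SD with
#' n-1 denominator) to create one representative individual per species, then
#' derives the aspect ratio and proportional tubercle position from the
#' averaged metrics (ratio of means, not mean of ratios).
#'
#' @param measurements A data frame of specimen measurements with columns
#'   `species`, `group`, `tmt_length`, `tmt_width`, `tubercle_distance` and
#'   optionally `tubercle_to_trochlea` (as produced by
#'   [generate_morphometric_population()] or read from CSV).
#' @return A one-row tibble (class `species_summary`) with `n`, per-metric
#'   `*_mean` and `*_sd`, `aspect_ratio` and `tubercle_prop`. A single
#'   specimen yields SD 0 and sets the `single_specimen` flag column.
#' @examples
#' pop <- generate_morphometric_population(focal_species_specs()[[1]], seed = 1)
#' summarize_species(pop)
#' @export
summarize_species <- function(measurements) {
  measurements <- as_tibble(measurements)
  if (nrow(measurements) < 1L) abort("Need at least one measurement.")
  if (length(unique(measurements$species)) != 1L) {
    abort("All measurements must belong to a single species; got mixed species.")
  }
  n <- nrow(measurements)
  sd0 <- function(x) if (length(x) > 1L) sd(x) else 0
  if (n == 1L) warn("Single specimen: SDs reported as 0.")
  metrics <- intersect(
    c("tmt_length", "tmt_width", "tubercle_distance", "tubercle_to_trochlea"),
    names(measurements))
  sums <- measurements |>
    summarise(across(all_of(metrics),
                     list(mean = ~ mean(.x), sd = ~ sd0(.x)),
                     .names = "{.col}_{.fn}"))
  out <- dplyr::bind_cols(
    tibble(species = measurements$species[[1]],
           group = if ("group" %in% names(measurements))
             measurements$group[[1]] else NA_character_,
           n = n),
    sums)
  out$aspect_ratio <- aspect_ratio(out$tmt_length_mean, out$tmt_width_mean)
  out$tubercle_prop <- tubercle_proportion(out$tubercle_distance_mean,
                                           out$tmt_length_mean)
  out$single_specimen <- n == 1L
  class(out) <- c("species_summary", class(out))
  out
}

#' Summarize several species at once
#'
#' @param measurements Specimen measurements for one or more species.
#' @return A tibble with one [summarize_species()] row per species.
#' @export
summarize_all_species <- function(measurements) {
  measurements <- as_tibble(measurements)
  out <- measurements |>
    group_split(.data$species) |>
    map(summarize_species) |>
    list_rbind()
  class(out) <- c("species_summary", class(out))
  out
}

#' Mann-Whitney U test with both statistic conventions
#'
#' Computes the Mann-Whitney statistic in the convention of
#' [stats::wilcox.test()],
#' \eqn{U = \#\{(i,j): x_i > y_j\} + \frac12 \#\{x_i = y_j\}}, together with
#' the orientation-free form `W = min(U, n1*n2 - U)` often quoted in
#' comparative work (a sample entirely below the other gives W = U = 0). The p-value is exact (distribution of U over all label
#' assignments) when both samples are small and tie-free, and a
#' tie-corrected normal approximation otherwise.
#'
#' @param x,y Non-empty numeric samples.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return A one-row tibble with `U`, `U_complement`, `W`, `p_value`,
#'   `method` (`"exact"` or `"normal"`), `n1`, `n2`.
#' @examples
#' mann_whitney_u(c(0.14, 0.19, 0.22), c(0.29, 0.29, 0.34))  # W = 0
#' @export
mann_whitney_u <- function(x, y, alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (length(x) < 1L || length(y) < 1L) abort("Both samples must be non-empty.")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  # U (= #{x > y} + half ties) from the rank sum of x
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u_lt <- n1 * n2 - u
  ties <- length(unique(c(x, y))) < n1 + n2
  exact <- !ties && n1 * n2 <= 400
  p <- suppressWarnings(
    wilcox.test(x, y, alternative = alternative, exact = exact,
                correct = TRUE)$p.value)
  tibble(U = u, U_complement = u_lt, W = min(u, u_lt),
         p_value = min(p, 1), method = if (exact) "exact" else "normal",
         n1 = n1, n2 = n2)
}

#' Compare a metric between two groups
#'
#' Runs [mann_whitney_u()] on a chosen metric between two group labels, at an
#' explicit unit of analysis: species-representative values (one value per
#' species, the default for small focal samples) or pooled specimen-level
#' values.
#'
#' @param data A tibble holding the metric: either per-species summaries
#'   ([summarize_all_species()] output) or per-specimen measurements.
#' @param metric Name of the metric column to compare (string).
#' @param group Name of the group label column (default `"group"`).
#' @param alternative Passed to [mann_whitney_u()].
#' @return A one-row tibble with the group labels and medians, `U`, `W`,
#'   `p_value` and the test method.
#' @examples
#' specs <- focal_species_specs()
#' pops <- purrr::imap(specs, \(s, nm) generate_morphometric_population(s, seed = 1))
#' sums <- summarize_all_species(purrr::list_rbind(pops))
#' compare_groups(sums, "aspect_ratio")
#' @export
compare_groups <- function(data, metric, group = "group",
                           alternative = "two.sided") {
  data <- as_tibble(data)
  if (!metric %in% names(data)) abort(sprintf("No column `%s` in `data`.", metric))
  if (!group %in% names(data)) abort(sprintf("No column `%s` in `data`.", group))
  labs <- sort(unique(data[[group]]))
  if (length(labs) != 2L) abort("Exactly two groups are required.")
  x <- data[[metric]][data[[group]] == labs[[1]]]
  y <- data[[metric]][data[[group]] == labs[[2]]]
  res <- mann_whitney_u(x, y, alternative = alternative)
  dplyr::bind_cols(
    tibble(metric = metric, group_1 = labs[[1]], group_2 = labs[[2]],
           median_1 = median(x), median_2 = median(y)),
    res)
}

#' Read / write morphometric specimen CSV
#'
#' Plain-CSV persistence for specimen measurement tables (columns
#' `specimen_id`, `species`, `group`, `tmt_length`, `tmt_width`,
#' `tubercle_distance`, optional `tubercle_to_trochlea`, `extinct`).
#'
#' @param path CSV file path.
#' @param measurements A specimen measurement tibble.
#' @return `read_morphometric_csv()` returns a tibble;
#'   `write_morphometric_csv()` returns `path` invisibly.
#' @export
read_morphometric_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' @rdname read_morphometric_csv
#' @export
write_morphometric_csv <- function(measurements, path) {
  readr::write_csv(as_tibble(measurements), path)
  invisible(path)
}
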