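#' Proportional growth in standard length
#'
#' Growth is the proportional increase in standard length over the exposure
#' period, `(final_sl - initial_sl) / initial_sl`. Shrinkage is not censored,
#' so negative values are returned as-is.
#'
#' @param initial_sl initial standard length in mm (> 0). Vectorised.
#' @param final_sl final standard length in mm (`NA` for non-survivors).
#' @return Numeric vector of proportional growth.
#' @export
compute_growth <- function(initial_sl, final_sl) {
  if (any(!is.na(initial_sl) & initial_sl <= 0))
    stop("initial_sl must be positive", call. = FALSE)
  (final_sl - initial_sl) / initial_sl
}

#' Composite fitness: survival times growth
#'
#' Composite fitness equals growth for survivors and zero for non-survivors
#' (growth cannot be measured on fish that were not recovered). By default
#' negative composite values for shrinking survivors are kept; set
#' `floor_at_zero = TRUE` to clamp them at zero.
#'
#' @param survived 0/1 survival indicator. Vectorised.
#' @param growth proportional growth; must be non-missing wherever
#'   `survived == 1`.
#' @param floor_at_zero clamp negative composite values at 0 (default `FALSE`).
#' @return Numeric vector of composite fitness.
#' @export
compute_composite <- function(survived, growth, floor_at_zero = FALSE) {
  if (any(!survived %in% c(0, 1)))
    stop("survived must be 0 or 1", call. = FALSE)
  if (any(survived == 1 & is.na(growth)))
    stop("growth missing for survivor(s)", call. = FALSE)
  out <- ifelse(survived == 0, 0, growth)
  if (floor_at_zero) out <- pmax(out, 0)
  out
}

#' Build per-hybrid fitness records from field measurements
#'
#' Derives growth and composite fitness from survival and standard-length
#' measurements and validates the record invariants (non-survivors have no
#' final length and composite 0; survivors have composite equal to growth).
#'
#' @param data data frame with columns `sample_id`, `survived`, `initial_sl`
#'   and `final_sl` (`NA` for non-survivors).
#' @param floor_composite_at_zero clamp negative composite at zero
#'   (default `FALSE`; shrinkage is not censored).
#' @return The input with `growth` and `composite` columns added, classed
#'   `fitness_records`.
#' @export
fitness_records <- function(data, floor_composite_at_zero = FALSE) {
  need <- c("sample_id", "survived", "initial_sl", "final_sl")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols))
    stop("fitness table missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(data$sample_id)) stop("duplicate sample_id", call. = FALSE)
  if (any(data$survived == 0 & !is.na(data$final_sl)))
    stop("non-survivors cannot have a final standard length", call. = FALSE)
  data$growth <- compute_growth(data$initial_sl, data$final_sl)
  data$composite <- compute_composite(data$survived, data$growth,
                                      floor_at_zero = floor_composite_at_zero)
  data$survival <- as.numeric(data$survived)
  class(data) <- c("fitness_records", "data.frame")
  data
}

#' Read a hybrid fitness table from CSV
#'
#' @param path CSV with columns `sample_id, survived, initial_sl, final_sl`.
#' @param ... passed to [fitness_records()].
#' @return A `fitness_records` data frame.
#' @export
read_fitness_table <- function(path, ...) {
  fitness_records(utils::read.csv(path, stringsAsFactors = FALSE), ...)
}
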