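#' Total wing area from spread-wing measurements
#'
#' Total lifting area is the area of both wings plus the body strip
#' between the wing roots:
#' `A_tot = 2 * A_w + C_r * (B - 2 * E)`,
#' where `A_w` is the area of a single spread wing, `C_r` the root chord
#' (wing width at its proximal border), `B` the wingspan, and `E` the wing
#' extent (distance from the root chord to the most distant feather tip).
#' Units must be internally consistent per specimen (meters and square
#' meters recommended).
#'
#' @param A_w Single-wing area.
#' @param C_r Root chord.
#' @param B Wingspan.
#' @param E Wing extent; must satisfy `2 * E <= B`.
#' @return Total area, strictly positive.
#' @export
#' @examples
#' total_wing_area(A_w = 0.4, C_r = 0.2, B = 2, E = 0.9)  # 0.84
total_wing_area <- function(A_w, C_r, B, E) {
  if (any(A_w <= 0) || any(C_r < 0) || any(B <= 0) || any(E < 0)) {
    stop("wing measurements must be positive", call. = FALSE)
  }
  if (any(B - 2 * E < 0)) {
    stop("inconsistent measurement: wing extents exceed half the wingspan (B - 2E < 0)",
         call. = FALSE)
  }
  2 * A_w + C_r * (B - 2 * E)
}

#' Wing aspect ratio
#'
#' `AR = B^2 / A_tot`: wingspan squared over total wing area. The aspect
#' ratio is the wing characteristic most influential for long-distance
#' flight efficiency and serves as the flight-efficiency proxy throughout
#' the package. Dimensionless and scale-invariant.
#'
#' @param B Wingspan.
#' @param A_tot Total wing area, see [total_wing_area()].
#' @return Aspect ratio.
#' @export
#' @examples
#' aspect_ratio(B = 2, A_tot = 0.84)
aspect_ratio <- function(B, A_tot) {
  if (any(B <= 0) || any(A_tot <= 0)) {
    stop("wingspan and area must be positive", call. = FALSE)
  }
  B^2 / A_tot
}

#' Species mean aspect ratios from a wing-measurement table
#'
#' Computes one aspect ratio per specimen and averages within species
#' (the default), or first averages the raw measurements within species
#' and takes the aspect ratio of the mean wing (`method = "ar_of_means"`,
#' useful when wingspans and wing areas come from unpaired sources).
#' Species means outside the typical avian range of 3-20 trigger a
#' warning as a data-quality check.
#'
#' @param wings Data frame with columns `specimen_id`, `species`, `B`,
#'   `A_w`, `C_r`, `E` (meters / square meters).
#' @param method `"mean_ar"` (mean of per-specimen ARs, default) or
#'   `"ar_of_means"`.
#' @return A tibble: `species`, `mean_AR`, `n_specimens`.
#' @export
species_aspect_ratio <- function(wings, method = c("mean_ar", "ar_of_means")) {
  method <- match.arg(method)
  wings <- tibble::as_tibble(wings)
  need <- c("species", "B", "A_w", "C_r", "E")
  miss <- setdiff(need, names(wings))
  if (length(miss)) stop("wings missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  out <- if (method == "mean_ar") {
    wings |>
      dplyr::mutate(.ar = aspect_ratio(
        .data$B, total_wing_area(.data$A_w, .data$C_r, .data$B, .data$E))) |>
      dplyr::group_by(.data$species) |>
      dplyr::summarise(mean_AR = mean(.data$.ar),
                       n_specimens = dplyr::n(), .groups = "drop")
  } else {
    wings |>
      dplyr::group_by(.data$species) |>
      dplyr::summarise(dplyr::across(c("B", "A_w", "C_r", "E"), mean),
                       n_specimens = dplyr::n(), .groups = "drop") |>
      dplyr::mutate(mean_AR = aspect_ratio(
        .data$B, total_wing_area(.data$A_w, .data$C_r, .data$B, .data$E))) |>
      dplyr::select("species", "mean_AR", "n_specimens")
  }
  if (any(out$mean_AR < 3 | out$mean_AR > 20)) {
    warning("species mean aspect ratio outside the typical avian range [3, 20]",
            call. = FALSE)
  }
  dplyr::arrange(out, .data$species)
}
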