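# Per-patient cell densities on TMA cores.
#
# Duplicate cores are combined by pooling counts and areas (ratio of sums),
# which keeps the estimate unbiased when evaluable areas differ between
# cores; the whole-core value is then an exact area-weighted mean of the
# tumor and stroma values.

#' Compute CK+ and double-positive cell densities per patient
#'
#' For each patient and compartment (tumor, stroma, and the whole core as
#' their pooled union), counts gate-positive (CK+) cells and
#' double-positive cells (CK+ and marker-positive on the same cell) across
#' all of the patient's cores and divides by the summed compartment area.
#'
#' @param cells Data frame with `patient_id`, `core_id`, `compartment`
#'   (`"tumor"`/`"stroma"`), a logical gate column `pos_CK`, and one
#'   logical `pos_<marker>` column per additional marker (`NA` allowed;
#'   `NA` never counts as positive).
#' @param areas Data frame with `patient_id`, `core_id`, `compartment`,
#'   `area_mm2`. Cores whose total area is zero or missing are excluded
#'   with a warning; a patient left with no cores gets `NA` densities.
#' @return A tibble, one row per patient: `ck_density_<cmp>`,
#'   `<marker>_ck_density_<cmp>` for each marker and compartment in
#'   `whole`, `tumor`, `stroma` (cells per mm^2), plus `area_<cmp>` and
#'   `n_cores`.
#' @examples
#' cells <- tibble::tibble(
#'   patient_id = 1, core_id = 1,
#'   compartment = rep(c("tumor", "stroma"), c(140, 22)),
#'   pos_CK = rep(c(TRUE, TRUE), c(140, 22)),
#'   pos_NRF2 = rep(c(TRUE, FALSE, TRUE, FALSE), c(40, 100, 2, 20))
#' )
#' areas <- tibble::tibble(patient_id = 1, core_id = 1,
#'                         compartment = c("tumor", "stroma"),
#'                         area_mm2 = c(0.5, 0.5))
#' compute_densities(cells, areas)
#' @export
compute_densities <- function(cells, areas) {
  need_c <- c("patient_id", "core_id", "compartment", "pos_CK")
  if (!all(need_c %in% names(cells))) {
    stop("`cells` must have columns: ",
         paste(setdiff(need_c, names(cells)), collapse = ", "))
  }
  need_a <- c("patient_id", "core_id", "compartment", "area_mm2")
  if (!all(need_a %in% names(areas))) {
    stop("`areas` must have columns: ",
         paste(setdiff(need_a, names(areas)), collapse = ", "))
  }
  markers <- sub("^pos_", "", grep("^pos_", names(cells), value = TRUE))
  markers <- setdiff(markers, "CK")

  all_patients <- sort(unique(c(cells$patient_id, areas$patient_id)))
  bad_core <- unique(areas$core_id[!is.finite(areas$area_mm2) |
                                     areas$area_mm2 <= 0])
  # a core is dropped outright if any of its compartment areas is unusable
  if (length(bad_core) > 0) {
    warning(length(bad_core),
            " core(s) with zero or missing area excluded from densities")
    areas <- areas[!areas$core_id %in% bad_core, ]
    cells <- cells[!cells$core_id %in% bad_core, ]
  }
  missing_core <- setdiff(unique(cells$core_id), unique(areas$core_id))
  if (length(missing_core) > 0) {
    stop("cells reference core_id(s) absent from the area table: ",
         paste(utils::head(missing_core, 5), collapse = ", "))
  }

  area_pc <- areas |>
    dplyr::group_by(.data$patient_id, .data$compartment) |>
    dplyr::summarise(area = sum(.data$area_mm2), .groups = "drop")
  n_cores <- areas |>
    dplyr::distinct(.data$patient_id, .data$core_id) |>
    dplyr::count(.data$patient_id, name = "n_cores")

  counts <- cells |>
    dplyr::group_by(.data$patient_id, .data$compartment) |>
    dplyr::summarise(
      ck = sum(.data$pos_CK, na.rm = TRUE),
      dplyr::across(dplyr::all_of(paste0("pos_", markers)),
                    ~ sum(.x & .data$pos_CK, na.rm = TRUE)),
      .groups = "drop"
    )

  tab <- dplyr::left_join(area_pc, counts,
                          by = c("patient_id", "compartment"))
  cnt_cols <- c("ck", paste0("pos_", markers))
  tab <- tab |>
    dplyr::mutate(dplyr::across(dplyr::all_of(cnt_cols),
                                ~ dplyr::coalesce(.x, 0L)))
  whole <- tab |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(compartment = "whole", area = sum(.data$area),
                     dplyr::across(dplyr::all_of(cnt_cols), sum),
                     .groups = "drop")
  tab <- dplyr::bind_rows(tab, whole)

  dens_cols <- c(ck = "ck_density",
                 stats::setNames(paste0(tolower(markers), "_ck_density"),
                                 paste0("pos_", markers)))
  for (i in seq_along(cnt_cols)) {
    tab[[dens_cols[[i]]]] <- tab[[cnt_cols[i]]] / tab$area
  }
  tab <- tab[, c("patient_id", "compartment", "area", unname(dens_cols))]

  out <- tab |>
    tidyr::pivot_wider(names_from = "compartment",
                       values_from = dplyr::all_of(c("area", unname(dens_cols))),
                       names_sep = "_") |>
    dplyr::left_join(n_cores, by = "patient_id") |>
    dplyr::arrange(.data$patient_id)

  # patients whose every core was excluded -> NA row; guarantee the full
  # column set even when no core survives
  expected <- c(paste0(rep(c("area", unname(dens_cols)), each = 3), "_",
                       c("whole", "tumor", "stroma")), "n_cores")
  for (col in setdiff(expected, names(out))) out[[col]] <- NA_real_
  lost <- setdiff(all_patients, out$patient_id)
  if (length(lost) > 0) {
    out <- dplyr::bind_rows(out, tibble::tibble(patient_id = lost)) |>
      dplyr::arrange(.data$patient_id)
  }
  out
}
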