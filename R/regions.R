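#' Default region hierarchy and sampled volumes
#'
#' The three functional composites and their component ROIs, with the group
#' mean sampled volumes (mm^3) used as default weights when subject-specific
#' volumes are unavailable: Association Cortex (DLPFC, OFC, MPFC, ACC),
#' Sensory Cortex (PC, OC) and the limbic Medial Temporal Lobe (AMY, HIP,
#' ENT, PHG).
#'
#' @return List with `volumes` (named vector, mm^3) and `composites`
#'   (named list of component-region name vectors).
#' @export
default_regions <- function() {
  list(
    volumes = c(DLPFC = 19390, OFC = 10260, MPFC = 5001, ACC = 2587,
                PC = 74583, OC = 49286,
                AMY = 2410, HIP = 4729, ENT = 960, PHG = 6021),
    composites = list(
      `Association Cortex` = c("DLPFC", "OFC", "MPFC", "ACC"),
      `Sensory Cortex` = c("PC", "OC"),
      `Medial Temporal Lobe` = c("AMY", "HIP", "ENT", "PHG")
    )
  )
}

#' Validate a region configuration
#'
#' Checks that all volumes are positive, every composite member has a volume,
#' and composite memberships are disjoint.
#'
#' @param config List with `volumes` and `composites` as in
#'   [default_regions()].
#' @return The config, invisibly, or an error.
#' @export
validate_regions <- function(config) {
  stopifnot(is.list(config), !is.null(config$volumes), !is.null(config$composites))
  if (any(config$volumes <= 0)) stop("region volumes must be positive")
  members <- unlist(config$composites, use.names = FALSE)
  missing <- setdiff(members, names(config$volumes))
  if (length(missing)) {
    stop("composite members without volumes: ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(members)) {
    stop("composite memberships must be disjoint")
  }
  invisible(config)
}

#' Average left and right values of a bilateral region
#'
#' @param left_value,right_value Values of the same measure on each side.
#' @return Arithmetic mean.
#' @export
bilateral_average <- function(left_value, right_value) {
  (left_value + right_value) / 2
}

#' Volume-weighted composite of component-region values
#'
#' Composite value = sum(v_i * x_i) / sum(v_i). Used to aggregate VT or BP
#' values into the functional composites.
#'
#' @param component_values Values per component region.
#' @param component_volumes Sampled volumes per component region (mm^3).
#' @return The weighted mean.
#' @export
composite_value <- function(component_values, component_volumes) {
  if (length(component_values) != length(component_volumes)) {
    stop("values and volumes must have equal length")
  }
  if (any(component_volumes <= 0)) stop("volumes must be positive")
  sum(component_volumes * component_values) / sum(component_volumes)
}

#' Add composite rows to a per-region outcome table
#'
#' Given a table with one value per component region, appends the three
#' functional composites as volume-weighted averages.
#'
#' @param values Named vector of per-region values (names matching the
#'   config's volume names).
#' @param config Region configuration (default [default_regions()]);
#'   validated before use.
#' @return data.frame with columns `region`, `value`, `composite` (logical).
#' @export
composite_table <- function(values, config = default_regions()) {
  validate_regions(config)
  comp <- vapply(config$composites, function(members) {
    if (!all(members %in% names(values))) return(NA_real_)
    composite_value(values[members], config$volumes[members])
  }, numeric(1))
  rbind(
    data.frame(region = names(comp), value = unname(comp), composite = TRUE),
    data.frame(region = names(values), value = unname(values), composite = FALSE)
  )
}
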