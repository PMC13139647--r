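#' Stem wood volume from diameter and height
#'
#' `V = pi * (D/100)^2 / 4 * H * f` in cubic metres: the cylinder volume from
#' diameter at breast height (cm) and total height (m), reduced by a
#' dimensionless form factor accounting for stem taper (default 0.4, a
#' standard value for young plantation trees).
#'
#' @param d_cm Diameter at breast height, cm (> 0).
#' @param h_m Tree height, m (> 0).
#' @param form_factor Dimensionless form factor in (0, 1]; default 0.4.
#' @return Stem volume in m^3 (vectorised).
#' @export
wood_volume <- function(d_cm, h_m, form_factor = 0.4) {
  stopifnot(form_factor > 0, form_factor <= 1)
  if (any(d_cm <= 0) || any(h_m <= 0)) {
    stop("diameter and height must be positive")
  }
  pi * (d_cm / 100)^2 / 4 * h_m * form_factor
}

#' Volume parameters for productivity
#'
#' @param form_factor Form factor (default 0.4).
#' @param t1,t2 Census years (defaults 2012 and 2017); `t2 > t1`.
#' @return A `volume_params` list.
#' @export
volume_params <- function(form_factor = 0.4, t1 = 2012, t2 = 2017) {
  stopifnot(form_factor > 0, form_factor <= 1, t2 > t1)
  structure(list(form_factor = form_factor, t1 = t1, t2 = t2),
            class = "volume_params")
}

#' Annual wood productivity of one subplot
#'
#' Sums, over the trees alive at both censuses, the annualised stem-volume
#' increment `(V2 - V1) / (t2 - t1)`, reported in cm^3 per year
#' (1 m^3 = 1e6 cm^3). Trees dead by the second census contribute nothing
#' (their terminal volume is unknown). Negative per-tree increments —
#' measurement noise — are kept, so a subplot AWP can be non-positive; such
#' subplots must be excluded before gamma model fitting.
#'
#' @param records Data frame of tree records for one subplot, with columns
#'   `tree_id`, `D1_cm`, `H1_m`, `alive_t1`, `D2_cm`, `H2_m`, `alive_t2`.
#' @param params A [volume_params()].
#' @return List: `awp` (cm^3/yr), `n` trees contributing; `awp = 0`, `n = 0`
#'   when no tree survives.
#' @export
subplot_awp <- function(records, params = volume_params()) {
  if (anyDuplicated(records$tree_id)) {
    stop("duplicated tree_id in subplot records: ",
         paste(unique(records$tree_id[duplicated(records$tree_id)]),
               collapse = ", "))
  }
  live <- records[records$alive_t1 & records$alive_t2, , drop = FALSE]
  if (!nrow(live)) return(list(awp = 0, n = 0L))
  v1 <- wood_volume(live$D1_cm, live$H1_m, params$form_factor)
  v2 <- wood_volume(live$D2_cm, live$H2_m, params$form_factor)
  awp_m3 <- sum((v2 - v1) / (params$t2 - params$t1))
  list(awp = awp_m3 * 1e6, n = nrow(live))
}

.INVENTORY_COLS <- c("tree_id", "plot_id", "subplot_id", "species",
                     "D1_cm", "H1_m", "alive_t1", "D2_cm", "H2_m", "alive_t2")

#' Read and validate a two-census tree inventory
#'
#' The inventory CSV carries one row per tree with diameters (cm) and heights
#' (m) at both censuses and survival indicators. Validation: all declared
#' columns present; dimensions positive and non-missing wherever the tree is
#' alive at that census; offending rows are listed in the error. The mixture
#' type of a plot is derived from the number of distinct species planted in
#' it (1 = monoculture, otherwise mixture).
#'
#' @param path Path to the inventory CSV.
#' @return A data frame of validated tree records with added `mixture_type`
#'   and `richness` columns (plot-level).
#' @export
read_inventory <- function(path) {
  inv <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_inventory(inv)
}

#' Validate an in-memory inventory table
#'
#' @param inv Data frame with the inventory columns (see [read_inventory()]).
#' @return The validated table with `mixture_type` and `richness` added.
#' @export
validate_inventory <- function(inv) {
  missing_cols <- setdiff(.INVENTORY_COLS, names(inv))
  if (length(missing_cols)) {
    stop("inventory missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  inv$alive_t1 <- as.logical(inv$alive_t1)
  inv$alive_t2 <- as.logical(inv$alive_t2)
  bad1 <- inv$alive_t1 &
    (!is.finite(inv$D1_cm) | inv$D1_cm <= 0 |
     !is.finite(inv$H1_m) | inv$H1_m <= 0)
  bad2 <- inv$alive_t2 &
    (!is.finite(inv$D2_cm) | inv$D2_cm <= 0 |
     !is.finite(inv$H2_m) | inv$H2_m <= 0)
  bad <- which(bad1 | bad2)
  if (length(bad)) {
    stop("invalid dimensions for living trees at rows: ",
         paste(utils::head(bad, 20), collapse = ", "))
  }
  rich <- tapply(inv$species, inv$plot_id, function(s) length(unique(s)))
  inv$richness <- as.integer(rich[as.character(inv$plot_id)])
  inv$mixture_type <- ifelse(inv$richness == 1, "monoculture", "mixture")
  inv
}

#' Subplot-level AWP table from an inventory
#'
#' Groups validated tree records by plot and subplot and computes AWP for
#' each. Mixture type and richness are plot-level attributes carried through.
#'
#' @param inv Validated inventory (from [read_inventory()] or
#'   [validate_inventory()]).
#' @param params A [volume_params()].
#' @return Data frame: `plot_id`, `subplot_id`, `mixture_type`, `richness`,
#'   `n_trees`, `awp_cm3_yr`.
#' @export
awp_table <- function(inv, params = volume_params()) {
  keys <- unique(inv[, c("plot_id", "subplot_id", "mixture_type", "richness")])
  keys <- keys[order(keys$plot_id, keys$subplot_id), , drop = FALSE]
  res <- mapply(function(p, s) {
    rec <- inv[inv$plot_id == p & inv$subplot_id == s, , drop = FALSE]
    a <- subplot_awp(rec, params)
    c(a$awp, a$n)
  }, keys$plot_id, keys$subplot_id)
  out <- data.frame(plot_id = keys$plot_id, subplot_id = keys$subplot_id,
                    mixture_type = keys$mixture_type,
                    richness = keys$richness,
                    n_trees = as.integer(res[2, ]),
                    awp_cm3_yr = res[1, ])
  rownames(out) <- NULL
  out
}
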