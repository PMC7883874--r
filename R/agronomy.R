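#' Scale a quadrat sample weight to tonnes per hectare
#'
#' A weight of `w` grams harvested from `a` square metres corresponds to
#' `w / a` g m^-2, i.e. `w / a * 0.01` t ha^-1.
#'
#' @param weight_g sample weight in grams (>= 0).
#' @param quadrat_area_m2 quadrat area in square metres (default 0.25).
#' @return yield in t ha^-1.
#' @export
scale_to_per_hectare <- function(weight_g, quadrat_area_m2 = 0.25) {
  assert_that(all(quadrat_area_m2 > 0), "quadrat area must be positive")
  assert_that(all(weight_g >= 0), "sample weight cannot be negative")
  weight_g / quadrat_area_m2 * 0.01
}

#' Nitrogen amount from dry matter yield and N concentration
#'
#' `N (kg ha^-1) = DM (t ha^-1) * 1000 * N%/100`.
#'
#' @param dm_t_ha dry matter yield, t ha^-1 (>= 0).
#' @param n_conc_pct nitrogen concentration, percent of dry matter.
#' @return nitrogen amount in kg ha^-1.
#' @export
n_amount <- function(dm_t_ha, n_conc_pct) {
  assert_that(all(dm_t_ha >= 0) && all(n_conc_pct >= 0),
              "dry matter and N concentration must be non-negative")
  if (any(n_conc_pct > 10)) {
    warning("N concentration above 10% of DM is implausible for herbage")
  }
  dm_t_ha * 1000 * n_conc_pct / 100
}

#' Difference-method nitrogen fixation
#'
#' `N_Fix = N_L - N_R`: nitrogen amount of the fixing crop (legume pure
#' stand or mixture) minus that of the paired non-fixing pure-grass
#' reference.  Negative values are scientifically meaningful (the
#' reference outgrew the legume stand) and are kept, flagged via the
#' `"n_negative"` attribute.
#'
#' @param n_l,n_r nitrogen amounts in kg ha^-1 (vectors recycle).
#' @return N fixation in kg ha^-1 with attribute `n_negative`.
#' @export
nfix_difference <- function(n_l, n_r) {
  assert_that(all(n_l >= 0) && all(n_r >= 0),
              "nitrogen amounts must be non-negative")
  out <- n_l - n_r
  attr(out, "n_negative") <- sum(out < 0)
  out
}

#' Average duplicate quadrat samples and scale to per-hectare yields
#'
#' Duplicate quadrats of a plot-harvest are averaged before scaling; FM
#' and DM are then extrapolated to t ha^-1 and the nitrogen amount
#' computed from DM and the N concentration.
#'
#' @param samples data.frame with columns `plot_id`, `year`, `harvest`,
#'   `treatment`, `fresh_weight_g`, `dry_weight_g`, `quadrat_area_m2`,
#'   `n_conc_pct`.
#' @return data.frame with one row per plot-harvest and columns
#'   `FM_t_ha`, `DM_t_ha`, `N_conc_pct`, `N_amount_kg_ha`.
#' @export
aggregate_samples <- function(samples) {
  need <- c("plot_id", "year", "harvest", "treatment", "fresh_weight_g",
            "dry_weight_g", "quadrat_area_m2", "n_conc_pct")
  assert_that(all(need %in% names(samples)),
              paste("samples must contain columns:", paste(need, collapse = ", ")))
  assert_that(all(samples$dry_weight_g <= samples$fresh_weight_g),
              "dry weight exceeds fresh weight in at least one sample")
  key <- interaction(samples$plot_id, samples$year, samples$harvest, drop = TRUE)
  agg <- lapply(split(samples, key), function(d) {
    data.frame(plot_id = d$plot_id[1], year = d$year[1], harvest = d$harvest[1],
               treatment = d$treatment[1],
               FM_t_ha = scale_to_per_hectare(mean(d$fresh_weight_g),
                                              d$quadrat_area_m2[1]),
               DM_t_ha = scale_to_per_hectare(mean(d$dry_weight_g),
                                              d$quadrat_area_m2[1]),
               N_conc_pct = mean(d$n_conc_pct))
  })
  out <- do.call(rbind, agg)
  out$N_amount_kg_ha <- n_amount(out$DM_t_ha, out$N_conc_pct)
  rownames(out) <- NULL
  out
}

# Mixture family of a treatment label: clover-grass (CG, L_CG, G_CG) or
# lucerne-grass (LG, L_LG, G_LG).
mixture_of <- function(treatment) {
  ifelse(treatment %in% c("CG", "L_CG", "G_CG"), "CG", "LG")
}

is_pure_grass <- function(treatment) treatment %in% c("G_CG", "G_LG")

#' Difference-method N fixation table
#'
#' Applies the difference method to a ground-truth table: every
#' legume-bearing plot-harvest (mixture or legume pure stand) is paired
#' with the pure-grass reference of the same mixture family in the same
#' block; if that reference plot is missing for the harvest, the mean of
#' the remaining reference replicates of the treatment is used instead,
#' and the fallback is flagged.  Rows with no reference at all are dropped
#' with a message.  Pure-grass rows never receive an N fixation value.
#'
#' @param truth data.frame with `plot_id`, `year`, `harvest`, `treatment`,
#'   `block`, `N_amount_kg_ha`.
#' @return data.frame with columns `plot_id`, `year`, `harvest`,
#'   `treatment`, `block`, `N_L`, `N_R`, `NFix_kg_ha`, `reference`
#'   (`"block"` or `"treatment_mean"`), `negative` flag.
#' @export
nfix_table <- function(truth) {
  need <- c("plot_id", "year", "harvest", "treatment", "block", "N_amount_kg_ha")
  assert_that(all(need %in% names(truth)),
              paste("truth table must contain:", paste(need, collapse = ", ")))
  leg <- truth[!is_pure_grass(truth$treatment), , drop = FALSE]
  ref <- truth[is_pure_grass(truth$treatment), , drop = FALSE]
  rows <- vector("list", nrow(leg))
  dropped <- 0L
  for (k in seq_len(nrow(leg))) {
    r <- leg[k, ]
    ref_treat <- if (mixture_of(r$treatment) == "CG") "G_CG" else "G_LG"
    cand <- ref[ref$treatment == ref_treat & ref$year == r$year &
                ref$harvest == r$harvest, , drop = FALSE]
    hit <- cand[cand$block == r$block, , drop = FALSE]
    if (nrow(hit) == 1) {
      n_r <- hit$N_amount_kg_ha
      src <- "block"
    } else if (nrow(cand) > 0) {
      n_r <- mean(cand$N_amount_kg_ha)
      src <- "treatment_mean"
    } else {
      dropped <- dropped + 1L
      next
    }
    nf <- r$N_amount_kg_ha - n_r
    rows[[k]] <- data.frame(plot_id = r$plot_id, year = r$year,
                            harvest = r$harvest, treatment = r$treatment,
                            block = r$block, N_L = r$N_amount_kg_ha,
                            N_R = n_r, NFix_kg_ha = nf, reference = src,
                            negative = nf < 0)
  }
  if (dropped > 0) {
    message(sprintf("%d legume-bearing records dropped: no pure-grass reference", dropped))
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  rownames(out) <- NULL
  out
}

#' Annual cumulative yields
#'
#' Sums FM, DM (and N fixation when present) over the harvests of each
#' plot-year; the running totals after the final harvest are the annual
#' yields used for range checks and reporting.
#'
#' @param truth per-harvest table with `plot_id`, `year`, `treatment` and
#'   any of `FM_t_ha`, `DM_t_ha`, `N_amount_kg_ha`, `NFix_kg_ha`.
#' @return data.frame with one row per plot-year holding the sums.
#' @export
annual_totals <- function(truth) {
  vars <- intersect(c("FM_t_ha", "DM_t_ha", "N_amount_kg_ha", "NFix_kg_ha"),
                    names(truth))
  key <- interaction(truth$plot_id, truth$year, drop = TRUE)
  rows <- lapply(split(truth, key), function(d) {
    out <- data.frame(plot_id = d$plot_id[1], year = d$year[1],
                      treatment = d$treatment[1], n_harvests = nrow(d))
    for (v in vars) out[[v]] <- sum(d[[v]])
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
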