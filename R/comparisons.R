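# Assembly of the three setup comparisons (prone vs supine; immobilization
# devices; pancreas vs its segments) from long-format motion records, per
# motion direction, with Friedman omnibus tests and LSD-protected Conover
# post-hocs rendered as a homogeneous-group symbol table.

# build a blocks x treatments matrix from records; returns NULL (with a
# dropped-blocks log) when fewer than 2 complete blocks survive
design_matrix <- function(rec, treatment_col, block_cols, value_col) {
  treatments <- sort(unique(rec[[treatment_col]]))
  if (length(treatments) < 2) return(NULL)
  block <- interaction(rec[block_cols], drop = TRUE)
  m <- tapply(rec[[value_col]], list(block, rec[[treatment_col]]), function(v) {
    if (length(v) != 1) NA_real_ else v
  })
  m <- m[, treatments, drop = FALSE]
  complete <- stats::complete.cases(m)
  dropped <- rownames(m)[!complete]
  m <- m[complete, , drop = FALSE]
  if (nrow(m) < 2) return(structure(list(NULL), dropped = dropped)[[1]])
  attr(m, "dropped") <- dropped
  m
}

#' Run the setup-comparison suite on motion records
#'
#' For each motion direction (LL, AP, SI signed displacements; 3D
#' magnitudes) three complete-block Friedman designs are assembled from the
#' non-reference-phase records:
#' * `prone_vs_supine` — treatments = positions, blocks = device x phase
#'   (whole pancreas records);
#' * `devices` — treatments = devices, blocks = position x phase (whole
#'   pancreas records);
#' * `structures` — treatments = pancreas/head/body/tail, blocks =
#'   position x device x phase.
#'
#' With `scope = "pooled"` the dataset id joins the blocking factors so all
#' datasets are analyzed together; with `scope = "per_dataset"` each dataset
#' is tested separately. Blocks with missing cells (e.g. an unusable
#' position/device combination) are dropped and logged. The Conover
#' post-hoc runs only when the Friedman omnibus p-value is below `alpha`
#' (Fisher-LSD protection); comparisons with fewer than 2 complete blocks
#' are reported as not testable.
#'
#' @param records motion records data.frame (see [motion_records()])
#' @param alpha significance level
#' @param scope `"pooled"` or `"per_dataset"`
#' @param directions motion directions to test
#' @return nested list `result[[dataset]][[comparison]][[direction]]`, each
#'   entry a list with `design`, `friedman`, `posthoc` (NULL unless the
#'   omnibus is significant), `dropped_blocks`, `testable`
#' @export
build_comparison_suite <- function(records, alpha = 0.05,
                                   scope = c("pooled", "per_dataset"),
                                   directions = c(AXES, "D3")) {
  scope <- match.arg(scope)
  rec <- records[!records$is_reference, ]
  sets <- if (scope == "pooled") list(all = rec) else split(rec, rec$dataset)
  lapply(sets, function(rs) {
    extra_block <- if (scope == "pooled") "dataset" else character(0)
    panc <- rs[rs$structure == "pancreas", ]
    out <- list()
    for (dir in directions) {
      specs <- list(
        prone_vs_supine = list(data = panc, treatment = "position",
                               blocks = c(extra_block, "device", "phase")),
        devices = list(data = panc, treatment = "device",
                       blocks = c(extra_block, "position", "phase")),
        structures = list(data = rs, treatment = "structure",
                          blocks = c(extra_block, "position", "device", "phase")))
      for (cmp in names(specs)) {
        sp <- specs[[cmp]]
        m <- design_matrix(sp$data, sp$treatment, sp$blocks, dir)
        if (is.null(m)) {
          out[[cmp]][[dir]] <- list(design = NULL, friedman = NULL,
                                    posthoc = NULL, dropped_blocks = NULL,
                                    testable = FALSE)
          next
        }
        fr <- friedman_block_test(m)
        ph <- if (fr$p_value < alpha) conover_posthoc(m, alpha) else NULL
        out[[cmp]][[dir]] <- list(design = m, friedman = fr, posthoc = ph,
                                  dropped_blocks = attr(m, "dropped"),
                                  testable = TRUE)
      }
    }
    out
  })
}

#' Render a comparison suite as a homogeneous-group symbol table
#'
#' One row per treatment of each comparison, one column per motion
#' direction. A treatment carries its group symbols when the omnibus test
#' was significant; an empty cell means homogeneous behavior; `"-"` marks a
#' comparison that was not testable.
#'
#' @param suite a [build_comparison_suite()] result
#' @return data.frame (dataset, comparison, treatment, one column per
#'   direction)
#' @export
render_symbol_table <- function(suite) {
  rows <- list()
  for (ds in names(suite)) {
    for (cmp in names(suite[[ds]])) {
      dirs <- suite[[ds]][[cmp]]
      treatments <- NULL
      for (dir in names(dirs)) {
        if (!is.null(dirs[[dir]]$design)) {
          treatments <- colnames(dirs[[dir]]$design)
          break
        }
      }
      if (is.null(treatments)) treatments <- "(none)"
      for (tr in treatments) {
        row <- data.frame(dataset = ds, comparison = cmp, treatment = tr)
        for (dir in names(dirs)) {
          cell <- dirs[[dir]]
          row[[dir]] <- if (!cell$testable) "-"
                        else if (is.null(cell$posthoc)) ""
                        else unname(cell$posthoc$symbols[tr])
        }
        rows[[length(rows) + 1]] <- row
      }
    }
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Build a synthetic multi-patient cohort of motion records
#'
#' Emulates a small patient cohort: for each dataset (patient) and each
#' position/device combination a breathing phantom is configured with
#' controllable effect sizes, and its motion records are extracted. By
#' default records come from the phantom's analytic ground-truth COM
#' trajectories (`records_from = "truth"`), which gives exactly controlled
#' effects for validating the statistical machinery; with
#' `records_from = "masks"` the full voxel path (generate masks ->
#' partition -> COM) is used instead.
#'
#' Per-patient variability is modeled as a multiplicative amplitude factor
#' drawn once per dataset. Effects are injected multiplicatively:
#' `prone_si_factor` scales the SI amplitude in the prone position,
#' `device_si_factors` scales it per device, `segment_si_factors` (named
#' head/body/tail) replaces the default per-segment scaling in SI while the
#' other directions keep a common (segment-independent) amplitude.
#'
#' @param n_datasets number of synthetic patients
#' @param base_amplitude_mm named (LL, AP, SI) whole-gland amplitude in mm
#' @param segment_factors per-segment multiplier applied to all directions
#' @param segment_si_factors optional per-segment SI multiplier overriding
#'   `segment_factors` along SI
#' @param prone_si_factor SI amplitude multiplier in the prone position
#' @param device_si_factors named per-device SI multiplier
#' @param patient_sd relative spread of the per-patient amplitude factor
#' @param records_from `"truth"` or `"masks"`
#' @param grid_shape,seed passed to the phantom configuration
#' @return motion records data.frame over the whole cohort
#' @export
build_synthetic_cohort <- function(n_datasets = 5,
                                   base_amplitude_mm = c(LL = 3.0, AP = 1.0, SI = 3.75),
                                   segment_factors = c(head = 0.8, body = 1.0, tail = 1.2),
                                   segment_si_factors = NULL,
                                   prone_si_factor = 1,
                                   device_si_factors = c(vacuum = 1, mask = 1, compressor = 1),
                                   patient_sd = 0.15,
                                   records_from = c("truth", "masks"),
                                   grid_shape = c(96L, 96L, 25L),
                                   seed = 1L) {
  records_from <- match.arg(records_from)
  set.seed(seed)
  patient_factor <- exp(stats::rnorm(n_datasets, sd = patient_sd))
  positions <- c("prone", "supine")
  recs <- list()
  for (d in seq_len(n_datasets)) {
    for (pos in positions) {
      for (dev in names(device_si_factors)) {
        amp <- outer(segment_factors, base_amplitude_mm * patient_factor[d])
        colnames(amp) <- AXES
        rownames(amp) <- c("head", "body", "tail")
        if (!is.null(segment_si_factors))
          amp[, "SI"] <- segment_si_factors *
            base_amplitude_mm["SI"] * patient_factor[d]
        if (pos == "prone") amp[, "SI"] <- amp[, "SI"] * prone_si_factor
        amp[, "SI"] <- amp[, "SI"] * device_si_factors[[dev]]
        cfg <- phantom_config(grid_shape = grid_shape, amplitude_mm = amp,
                              position_label = pos, device_label = dev,
                              seed = seed + 1000L * d)
        ph <- generate_phantom(cfg, render_intensity = FALSE)
        if (records_from == "truth") {
          rec <- motion_records_from_traj(ph$truth_com_mm,
                                          dataset = paste0("dataset", d),
                                          position = pos, device = dev)
        } else {
          part <- partition_4d(ph$masks, ph$spacing_mm, seed = seed + d)
          rec <- motion_records(part, dataset = paste0("dataset", d),
                                position = pos, device = dev)
        }
        recs[[length(recs) + 1]] <- rec
      }
    }
  }
  do.call(rbind, c(recs, make.row.names = FALSE))
}
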