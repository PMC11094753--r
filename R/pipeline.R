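# end-to-end reproduction pipeline: geometry summaries, pair scan,
# branch-angle scan, analytic gains, synthetic tables + fits, with a hashed
# manifest for determinism checks

#' Configuration for a full reproduction run
#'
#' Collects every setting of [run_reproduction()] with defaults matching the
#' study conditions (R = 2 µm, l = 10 µm, separations 5-25 µm in 5 µm steps,
#' 5-degree branch-angle grid). A single global `seed` deterministically
#' derives per-stage seeds, so stages are independently reproducible.
#'
#' @param out_dir Output directory.
#' @param seed Global integer seed.
#' @param d Proximity distances (µm) for interaction areas.
#' @param D Access reach (µm).
#' @param pixel_size,access_pixel_size Grid resolutions (µm) for area and
#'   access work.
#' @param angle_step Ray angular increment (radians).
#' @param domain_extent Square window side (µm) for scene summaries.
#' @param separations Pair-scan separations (µm).
#' @param n_instances Random-angle instances per separation.
#' @param pair_pixel_size Pair-scan grid resolution (µm).
#' @param branch_angles Branch-angle grid (degrees).
#' @param branch_pixel_size Branch-scan grid resolution (µm).
#' @param R0,r_s,L Conservation-budget parameters (µm).
#' @param gain_d Proximities (µm) for the analytic gain table.
#' @param n_plastids,n_cells Synthetic-data sizes.
#' @return A `<reproduction_config>` list.
#' @export
reproduction_config <- function(out_dir = tempfile("stromules-run-"),
                                seed = 1,
                                d = c(0.5, 1, 2, 5),
                                D = 1,
                                pixel_size = 0.05,
                                access_pixel_size = 0.1,
                                angle_step = 0.1,
                                domain_extent = 40,
                                separations = seq(5, 25, by = 5),
                                n_instances = 20,
                                pair_pixel_size = 0.1,
                                branch_angles = seq(60, 180, by = 5),
                                branch_pixel_size = 0.05,
                                R0 = 2, r_s = 0.3, L = 10,
                                gain_d = c(0.5, 1, 2),
                                n_plastids = 2000,
                                n_cells = 200) {
  cfg <- as.list(environment())
  structure(cfg, class = "reproduction_config")
}

#' Run the full reproduction pipeline
#'
#' Produces, under `config$out_dir`:
#' 1. `geometry_summary.csv` — interaction areas, max access and mean
#'    distance for the four stromule arrangements (none, single, double,
#'    branched) at matched total length.
#' 2. `pair_scan.csv` — union interaction area of a plastid pair over the
#'    separation grid.
#' 3. `branch_angle.csv` — interaction area over the branch-angle grid with
#'    the optimum flagged.
#' 4. `analytic_gains.csv` — closed-form relative interaction gains, 2D and
#'    3D, membrane and volume conservation.
#' 5. `synthetic_*`/`fits.csv` — seeded stressed and unstressed measurement
#'    tables and their Poisson / log-normal / power-law fits.
#'
#' A `manifest.json` lists every file with its MD5 hash plus the seed and a
#' hash of the configuration; identical config and seed give identical
#' manifest hashes. On error, partial outputs are removed.
#'
#' @param config A `<reproduction_config>`.
#' @return Invisibly, the manifest as a tibble (`file`, `md5`, `bytes`).
#' @export
run_reproduction <- function(config = reproduction_config()) {
  if (!inherits(config, "reproduction_config")) {
    abort("`config` must come from `reproduction_config()`.")
  }
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(tbl, name) {
    p <- file.path(out, name)
    readr::write_csv(tbl, p)
    written <<- c(written, p)
    p
  }
  tryCatch({
      # 1. geometry summary across arrangements
      labels <- c("none", "single", "double", "branched")
      geometry_summary <- purrr::map_dfr(labels, function(lab) {
        g <- plastid_geometry(lab, body_radius = config$R0,
                              stromule_length = if (lab == "none") 0 else config$L)
        s <- summarize_scene(g, d = config$d, D = config$D,
                             pixel_size = config$pixel_size,
                             access_pixel_size = config$access_pixel_size,
                             angle_step = config$angle_step,
                             domain_extent = config$domain_extent)
        dplyr::mutate(s$areas,
                      geometry_label = lab,
                      max_access = s$max_access,
                      mean_distance_um = s$mean_distance,
                      .before = 1)
      })
      emit(geometry_summary, "geometry_summary.csv")

      # 2. pair-separation scan
      pair <- pair_separation_scan(
        separations = config$separations, config = "single",
        n_instances = config$n_instances,
        seed = stage_seed(config$seed, 2),
        body_radius = config$R0, stromule_length = config$L,
        d = config$d[which.min(abs(config$d - 1))],
        pixel_size = config$pair_pixel_size
      )
      emit(pair, "pair_scan.csv")

      # 3. branch-angle scan
      branch <- branch_angle_scan(
        body_radius = config$R0, stromule_length = config$L,
        d = config$d[which.min(abs(config$d - 1))],
        angles = config$branch_angles,
        pixel_size = config$branch_pixel_size
      )
      emit(branch, "branch_angle.csv")

      # 4. analytic gains
      gains <- interaction_gain_table(R0 = config$R0, r_s = config$r_s,
                                      L = config$L, d = config$gain_d)
      emit(gains, "analytic_gains.csv")

      # 5. synthetic tables + fits
      fits <- list()
      for (cond in c("stressed", "unstressed")) {
        ds <- generate_stromule_table(
          config$n_plastids, preset = cond,
          seed = stage_seed(config$seed, if (cond == "stressed") 5 else 6)
        )
        emit(ds$plastids, sprintf("synthetic_%s_plastids.csv", cond))
        emit(ds$lengths, sprintf("synthetic_%s_lengths.csv", cond))
        pf <- fit_poisson_counts(ds$plastids)
        lf <- fit_lognormal_lengths(ds$lengths)
        fits[[paste0(cond, "_poisson")]] <- dplyr::mutate(
          glance(pf), model = "poisson", condition = cond,
          measured_sf = stromule_frequency(ds$plastids), .before = 1
        )
        fits[[paste0(cond, "_lognormal")]] <- dplyr::mutate(
          glance(lf), model = "lognormal", condition = cond, .before = 1
        )
      }
      cells <- generate_cell_table(config$n_cells,
                                   seed = stage_seed(config$seed, 7))
      emit(cells$cells, "synthetic_cells.csv")
      plf <- fit_powerlaw_density(cells$cells)
      fits[["powerlaw"]] <- dplyr::mutate(
        glance(plf), model = "powerlaw", condition = "unchallenged", .before = 1
      )
      emit(dplyr::bind_rows(fits), "fits.csv")

      manifest <- tibble(
        file = basename(written),
        md5 = unname(tools::md5sum(written)),
        bytes = unname(file.size(written))
      )
      meta <- list(
        package = "stromules",
        version = as.character(utils::packageVersion("stromules")),
        seed = config$seed,
        config_hash = rlang::hash(unclass(config)[setdiff(names(config), "out_dir")]),
        files = manifest
      )
      jsonlite::write_json(meta, file.path(out, "manifest.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      invisible(manifest)
    }, error = function(e) {
      unlink(written)
      abort(paste0("Reproduction run failed (partial outputs removed): ",
                   conditionMessage(e)), parent = e)
    })
}
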