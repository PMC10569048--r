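# Condensation-path orchestration: bin frames by interhelical distance,
# assemble the solvation-shell observable table (bound waters, hydrogen
# bonds, cation coordination, stored energy) relative to the free state,
# and bundle a full synthetic-study report with provenance.

#' Condensation-path specification
#'
#' Uniform bins in interhelical distance with declared condensed and free
#' states. Defaults follow the study design: bins of 0.5 angstrom
#' (0.05 nm), condensed state at d = 2.8 nm, free state at d = 4.0 nm,
#' 500-snapshot budget.
#'
#' @param d_min,d_max path range, nm.
#' @param delta_d bin width, nm (default 0.05 = 0.5 angstrom).
#' @param d_bound,d_free state definitions, nm.
#' @param snapshots snapshot budget for path construction.
#' @return list of class `ha_pathspec` with bin `edges` and `centers`.
#' @export
path_spec <- function(d_min = 2.4, d_max = 4.0, delta_d = 0.05,
                      d_bound = 2.8, d_free = 4.0, snapshots = 500) {
  edges <- seq(d_min, d_max + 1e-9, by = delta_d)
  if (d_bound < d_min || d_bound > d_max || d_free < d_min || d_free > d_max) {
    abort("state distances must lie inside the bin range", class = "ha_domain_error")
  }
  structure(list(edges = edges, centers = (head(edges, -1) + tail(edges, -1)) / 2,
                 delta_d = delta_d, d_bound = d_bound, d_free = d_free,
                 snapshots = snapshots),
            class = "ha_pathspec")
}

#' Assign frames to interhelical-distance bins
#'
#' Computes the per-frame interhelical distance from least-squares axis fits
#' through each helix's phosphates and assigns every frame to a path bin.
#' Frames whose axis fit fails are skipped with a warning.
#'
#' @param window an `ha_trajectory` containing both helices.
#' @param pathspec a [path_spec()].
#' @return tibble with `frame`, `d` (nm), `bin` (integer; NA outside the
#'   range); attribute `occupancy` tabulates frames per bin.
#' @export
bin_frames_by_distance <- function(window, pathspec) {
  at <- window$atoms
  ph1 <- intersect(select_group(at, "helix1"), select_group(at, "phosphate_backbone"))
  ph2 <- intersect(select_group(at, "helix2"), select_group(at, "phosphate_backbone"))
  fr_ids <- frame_indices(window)
  skipped <- integer(0)
  rows <- purrr::map_dfr(fr_ids, function(i) {
    fr <- window$frames[window$frames$frame == i, ]
    d <- tryCatch({
      a1 <- fit_axis(as.matrix(fr[match(ph1, fr$atom), c("x", "y", "z")]))
      a2 <- fit_axis(as.matrix(fr[match(ph2, fr$atom), c("x", "y", "z")]))
      sqrt(sum((a1$origin[1:2] - a2$origin[1:2])^2)) / 10
    }, error = function(e) NA_real_)
    tibble(frame = i, d = d)
  })
  if (anyNA(rows$d)) {
    skipped <- rows$frame[is.na(rows$d)]
    warn(paste0("axis fit failed for frames: ", paste(head(skipped, 10), collapse = ", ")),
         class = "ha_fit_failure")
    rows <- rows[!is.na(rows$d), ]
  }
  bin <- findInterval(rows$d, pathspec$edges, rightmost.closed = TRUE)
  bin[bin < 1 | bin > length(pathspec$centers)] <- NA_integer_
  rows$bin <- bin
  occ <- table(factor(bin, levels = seq_along(pathspec$centers)))
  structure(rows, occupancy = as.integer(occ), skipped = skipped)
}

# per-snapshot solvation-shell observables (single-frame structure)
.snapshot_observables <- function(st, shells = c(R1 = 3.5, R2 = 6.0, R3 = 10.0),
                                  cation_species = NULL) {
  w <- as_trajectory(st)
  at <- w$atoms
  cation_species <- cation_species %||% {
    g <- unique(at$group[grepl("^ion:", at$group)])
    if (length(g) > 0) g[1] else NULL
  }
  has_water <- any(at$group == "water")
  dna <- at$atom[!is.na(at$helix)]
  obs <- list(
    n_water_R1 = function() if (has_water) bound_waters(w, shells[["R1"]]) else NA_real_,
    n_hbond_R1 = function() if (has_water) hydrogen_bonds(w, shells[["R1"]]) else NA_real_,
    n_cation_R2 = function() .count_within(w, cation_species, shells[["R2"]], dna),
    n_cation_R3 = function() .count_within(w, cation_species, shells[["R3"]], dna),
    U_d = function() stored_energy(shell_charges(st, thickness = shells[["R3"]]))
  )
  vapply(obs, function(f) tryCatch(f(), error = function(e) NA_real_), numeric(1))
}

.count_within <- function(window, species, R, dna_ids) {
  if (is.null(species)) return(NA_real_)
  ids <- select_group(window$atoms, species)
  fr <- window$frames
  pts <- as.matrix(fr[match(ids, fr$atom), c("x", "y", "z")])
  ref <- as.matrix(fr[match(dna_ids, fr$atom), c("x", "y", "z")])
  sum(surface_distance(pts, ref, window$box) <= R)
}

#' Solvation-shell observables along the condensation path
#'
#' For a list of path snapshots (single-frame structures spanning the d
#' range), computes per-bin time averages of the bound-water count (R1),
#' hydrogen bonds (R1), cation coordination (R2 count, R3 count) and stored
#' electrostatic energy (R3), and reports each as the change relative to
#' the free state (the largest-d occupied bin), except the R2 cation count
#' which is reported absolutely.
#'
#' @param snapshots list of `ha_structure` snapshots (each built at a known
#'   d; d is recovered from construction metadata or by axis fitting).
#' @param pathspec a [path_spec()].
#' @param shells named radii, angstrom.
#' @param cation_species group name; defaults to the first `ion:*` group.
#' @return tibble of class `ha_path_profile`: one row per occupied bin with
#'   columns `d`, `n_frames`, `dN_water_R1`, `dN_hbond_R1`, `dN_cation_R3`,
#'   `N_cation_R2`, `dU_d`. Columns whose observable failed are NA.
#' @export
condensation_profile <- function(snapshots, pathspec,
                                 shells = c(R1 = 3.5, R2 = 6.0, R3 = 10.0),
                                 cation_species = NULL) {
  ds <- vapply(snapshots, function(st) {
    cons <- attr(st, "construction")
    if (!is.null(cons)) cons$separation else estimate_d_theta(st)$d
  }, numeric(1))
  obs <- t(vapply(snapshots, .snapshot_observables, numeric(5),
                  shells = shells, cation_species = cation_species))
  bin <- findInterval(ds, pathspec$edges, rightmost.closed = TRUE)
  ok <- bin >= 1 & bin <= length(pathspec$centers)
  tb <- as_tibble(obs[ok, , drop = FALSE]) %>%
    mutate(bin = bin[ok], d = pathspec$centers[bin[ok]])
  prof <- tb %>% group_by(.data$bin, .data$d) %>%
    summarise(across(c("n_water_R1", "n_hbond_R1", "n_cation_R2",
                       "n_cation_R3", "U_d"), ~ mean(.x)),
              n_frames = n(), .groups = "drop") %>%
    arrange(.data$d)
  ref <- prof[nrow(prof), ]
  out <- prof %>% mutate(
    dN_water_R1 = .data$n_water_R1 - ref$n_water_R1,
    dN_hbond_R1 = .data$n_hbond_R1 - ref$n_hbond_R1,
    dN_cation_R3 = .data$n_cation_R3 - ref$n_cation_R3,
    N_cation_R2 = .data$n_cation_R2,
    dU_d = .data$U_d - ref$U_d
  ) %>%
    select("d", "n_frames", "dN_water_R1", "dN_hbond_R1", "dN_cation_R3",
           "N_cation_R2", "dU_d")
  failed <- names(which(colSums(is.finite(as.matrix(out[, -(1:2)]))) == 0))
  if (length(failed) > 0) {
    warn(paste0("observables unavailable: ", paste(failed, collapse = ", ")),
         class = "ha_partial_profile")
  }
  structure(out, class = c("ha_path_profile", class(out)),
            shells = shells, reference_d = ref$d)
}

#' Run the full synthetic-study pipeline and bundle outputs
#'
#' Generates a duplex-pair condensation path with ions and waters, a toy
#' well-tempered metadynamics run, and writes every stage's outputs (TSV
#' profiles, HILLS file, free-energy tables, entropy report) into one
#' directory together with a machine-readable provenance manifest and a
#' human-readable summary. Stage failures are isolated and enumerated.
#'
#' @param config named list (or path to a YAML file) with optional entries:
#'   `seed`, `out_dir`, `n_bp`, `n_waters`, `n_cations`, `cation`
#'   (list with `species`, `valence`), `box` (angstrom 3-vector),
#'   `temperature`, `path` (list passed to [path_spec()]), `wtmd` (list
#'   passed to [run_langevin_wtmd()]), `snapshots_per_bin`.
#' @return list with `outputs` (named file paths), `failures` (named error
#'   messages), `ok` (TRUE when every stage succeeded), invisibly.
#' @export
full_report <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config) || is.null(config$out_dir)) {
    abort("config must be a list (or YAML file) with at least out_dir",
          class = "ha_usage_error")
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1L
  temperature <- config$temperature %||% 300
  box <- config$box %||% c(118, 118, 68)
  n_bp <- config$n_bp %||% 20L
  spec <- helix_spec(n_bp = n_bp)
  ps <- do.call(path_spec, config$path %||% list())
  cat_cfg <- config$cation %||% list(species = "Mg", valence = 2)
  collector <- new.env(parent = emptyenv())
  collector$outputs <- list()
  collector$failures <- list()
  record <- function(name, path) {
    collector$outputs[[name]] <- path
  }
  run_stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) e)
    if (inherits(res, "error")) {
      collector$failures[[name]] <- conditionMessage(res)
      NULL
    } else res
  }
  out_path <- function(f) file.path(config$out_dir, f)

  # --- synthetic condensation path ------------------------------------------
  per_bin <- config$snapshots_per_bin %||%
    max(1L, floor(ps$snapshots / length(ps$centers)))
  snapshots <- run_stage("synth", {
    purrr::flatten(purrr::map(seq_along(ps$centers), function(b) {
      purrr::map(seq_len(per_bin), function(k) {
        s <- seed + 1000L * b + k
        st <- build_duplex_pair(spec, separation = ps$centers[b],
                                theta = 0.25, box = box)
        st <- place_ions(st, cat_cfg$species, cat_cfg$valence,
                         mode = "helical_groove_chain",
                         count = config$n_cations %||% 20L,
                         chain_sigma = 2.0, seed = s)
        place_waters(st, count = config$n_waters %||% 200L, seed = s + 1L)
      })
    }))
  })
  if (!is.null(snapshots)) {
    st0 <- snapshots[[1]]
    run_stage("synth_write", {
      write_structure_pdb(st0, out_path("bound_state.pdb"))
      record("bound_state", out_path("bound_state.pdb"))
    })
  }

  # --- path observables ------------------------------------------------------
  run_stage("path", {
    prof <- condensation_profile(snapshots, ps)
    write_profile_tsv(prof, out_path("condensation_profile.tsv"),
                      metadata = list(stage = "path", seed = seed,
                                      reference_d = attr(prof, "reference_d")))
    record("condensation_profile", out_path("condensation_profile.tsv"))
  })

  # --- ion atmosphere on the bound state ------------------------------------
  run_stage("atmosphere", {
    w <- as_trajectory(snapshots[[1]])
    cyl <- cylindrical_concentration(w, paste0("ion:", cat_cfg$species))
    write_profile_tsv(cyl, out_path("cylindrical_concentration.tsv"),
                      metadata = list(stage = "atmosphere", seed = seed))
    sc <- excess_charge_by_shell(w)
    write_profile_tsv(sc, out_path("shell_charges.tsv"),
                      metadata = list(stage = "atmosphere",
                                      dna_charge = attr(sc, "dna_charge")))
    record("cylindrical_concentration", out_path("cylindrical_concentration.tsv"))
    record("shell_charges", out_path("shell_charges.tsv"))
  })

  # --- hydration -------------------------------------------------------------
  run_stage("hydration", {
    w <- as_trajectory(snapshots[[1]])
    ord <- tetrahedral_order(w)
    write_profile_tsv(ord$profile, out_path("tetrahedral_order.tsv"),
                      metadata = list(stage = "hydration",
                                      n_skipped = ord$n_skipped))
    record("tetrahedral_order", out_path("tetrahedral_order.tsv"))
  })

  # --- toy WTMD + FES --------------------------------------------------------
  run_stage("fes", {
    pot <- toy_potential_2d(temperature = temperature)
    wt_args <- config$wtmd %||% list(steps = 200000L, hill_stride = 250L)
    run <- do.call(run_langevin_wtmd,
                   c(list(potential = pot, seed = seed), wt_args))
    write_hills(run$hills, out_path("HILLS"))
    fes <- reconstruct_fes(run$hills, temperature = temperature)
    write_profile_tsv(export_polar(fes), out_path("fes_polar.tsv"),
                      metadata = list(stage = "fes", gamma = fes$bias_factor))
    prof <- project_1d(fes)
    write_profile_tsv(prof, out_path("fes_profile_d.tsv"),
                      metadata = list(stage = "fes"))
    dfv <- delta_f(prof, ps$d_bound, ps$d_free, n_bp = n_bp,
                   scale_to_bp = c(300, 500))
    write_profile_tsv(tibble(quantity = c("delta_f", "per_bp"),
                             value = c(dfv$delta_f, dfv$per_bp)),
                      out_path("delta_f.tsv"), metadata = list(stage = "fes"))
    record("hills", out_path("HILLS"))
    record("fes_polar", out_path("fes_polar.tsv"))
    record("fes_profile", out_path("fes_profile_d.tsv"))
    record("delta_f", out_path("delta_f.tsv"))
  })

  # --- entropy ---------------------------------------------------------------
  run_stage("entropy", {
    mk_state <- function(d, s) {
      st <- build_duplex_pair(spec, separation = d, theta = 0.25, box = box)
      st <- place_ions(st, cat_cfg$species, cat_cfg$valence,
                       mode = "helical_groove_chain",
                       count = config$n_cations %||% 20L, chain_sigma = 2.0,
                       seed = s)
      st <- place_waters(st, count = config$n_waters %||% 200L, seed = s + 1L)
      frames <- purrr::map(1:40, function(i) {
        tr <- sample_velocities(st, temperature, seed = s + i)
        f <- tr$frames; f$frame <- i; f
      })
      trajectory_window(st, bind_rows(frames), dt = 0.05)
    }
    rep_tbl <- entropy_change_report(mk_state(ps$d_bound, seed + 11L),
                                     mk_state(ps$d_free, seed + 77L),
                                     temperature = temperature)
    write_profile_tsv(rep_tbl, out_path("entropy_report.tsv"),
                      metadata = list(stage = "entropy", temperature = temperature))
    record("entropy_report", out_path("entropy_report.tsv"))
  })

  # --- provenance ------------------------------------------------------------
  manifest <- list(
    package = "helixatmos",
    version = as.character(utils::packageVersion("helixatmos")),
    r_version = R.version.string,
    seed = seed,
    config_hash = rlang::hash(config),
    config = config,
    outputs = collector$outputs,
    failures = collector$failures,
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, out_path("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  summary_lines <- c(
    "helixatmos full report",
    sprintf("seed %d, %d stage outputs, %d failures", seed,
            length(collector$outputs), length(collector$failures)),
    paste0("  output: ", unlist(collector$outputs)),
    if (length(collector$failures) > 0) {
      paste0("  FAILED ", names(collector$failures), ": ",
             unlist(collector$failures))
    }
  )
  writeLines(summary_lines, out_path("summary.txt"))
  invisible(list(outputs = collector$outputs, failures = collector$failures,
                 manifest = out_path("manifest.json"),
                 ok = length(collector$failures) == 0))
}
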