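# Study orchestration: specimens -> VOIs -> fabric + morphometry -> group
# statistics -> Table-style and stereoplot reports. Configuration is a single
# JSON file (or the equivalent in-memory list); group pooling is expressed in
# config so pooled designs (e.g. "human+fossil vs chimp") are config lines,
# not code.

#' Read / write a study configuration
#'
#' The configuration lists specimens (volume path or in-memory volume, voxel
#' spacing, group label, VOI centres/diameters per side and role) and the
#' statistics options (seed, Monte-Carlo draws, axial flag, outlier
#' exclusions, pooled comparisons).
#'
#' @param path JSON file.
#' @return A `study_config` list.
#' @export
read_study_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_study_config(cfg)
}

#' @rdname read_study_config
#' @param config a `study_config` list.
#' @export
write_study_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

validate_study_config <- function(cfg) {
  if (is.null(cfg$specimens) || !length(cfg$specimens))
    stop("config has no specimens")
  for (sp in cfg$specimens) {
    if (is.null(sp$id) || is.null(sp$group) || !nzchar(sp$group))
      stop("every specimen needs a non-empty id and group label")
    for (side in c("medial", "lateral")) {
      for (role in c("orientation", "morphometry")) {
        key <- paste(side, role, sep = "_")
        if (is.null(sp$vois[[key]]))
          stop(sprintf("specimen %s: missing %s VOI", sp$id, key))
      }
    }
  }
  if (is.null(cfg$stats)) cfg$stats <- list()
  if (is.null(cfg$stats$seed)) cfg$stats$seed <- 1L
  if (is.null(cfg$stats$n_draws)) cfg$stats$n_draws <- 1e4
  if (is.null(cfg$stats$axial)) cfg$stats$axial <- TRUE
  structure(cfg, class = "study_config")
}

voi_from_entry <- function(entry, role, side) {
  spherical_voi(unlist(entry$center), entry$diameter, role = role, side = side)
}

#' Analyse one specimen
#'
#' End-to-end chain for a single bone: (optionally) reorient along the long
#' axis, binarize if gray, extract the per-side orientation and morphometry
#' VOIs, and compute the 2D-PTO (MIL pooled over the 10 middle sagittal slices
#' of each orientation VOI, plus a specimen-level alpha pooled over both
#' sides), the 3D fabric (PTO axis + DA per side) and the morphometry summary
#' per side.
#'
#' @param entry one specimen entry of a `study_config`: fields `id`, `group`,
#'   `volume` (a [voxel_volume()]) or `path` (TIFF stack), optional
#'   `spacing_um`, optional `reorient` (logical or explicit axis), `vois` with
#'   `medial_orientation`, `lateral_orientation`, `medial_morphometry`,
#'   `lateral_morphometry` entries (each `center` + `diameter`).
#' @param n_slices sagittal slices per orientation VOI.
#' @param n_directions hemisphere directions for the 3D fabric.
#' @param seed seed for grid jitter.
#' @return Per-specimen record (list).
#' @export
run_specimen <- function(entry, n_slices = 10L, n_directions = 257L, seed = 1L) {
  vol <- if (!is.null(entry$volume)) entry$volume
         else read_stack(entry$path, spacing_um = entry$spacing_um)
  if (!is.null(entry$reorient)) {
    axis <- if (isTRUE(entry$reorient)) estimate_long_axis(vol)
            else unit3(unlist(entry$reorient))
    vol <- reorient(vol, axis)
  }
  if (!vol$binary) vol <- binarize_gradient(vol)

  sides <- c("medial", "lateral")
  per_side <- list()
  pooled_acc <- NULL; pooled_thetas <- NULL
  for (side in sides) {
    voi_o <- extract_voi(vol, voi_from_entry(entry$vois[[paste0(side, "_orientation")]],
                                             "orientation", side))
    voi_m <- extract_voi(vol, voi_from_entry(entry$vois[[paste0(side, "_morphometry")]],
                                             "morphometry", side))
    slices <- middle_sagittal_slices(voi_o$volume, n_slices)
    smasks <- middle_sagittal_slices(voi_o$mask, n_slices)
    prof <- mil_profile_2d(slices, smasks, seed = seed)
    o2d <- pto_2d(prof)
    fab <- fabric_voi(voi_o$volume, voi_o$mask, n_directions = n_directions,
                      seed = seed)
    morph <- morphometry_summary(voi_m$volume, voi_m$mask, fabric = fab,
                                 id = entry$id, side = side)
    per_side[[side]] <- list(orientation_2d = o2d, profile = prof,
                             fabric = fab, morphometry = morph)
    if (is.null(pooled_acc)) {
      pooled_acc <- cbind(prof$length, prof$crossings)
      pooled_thetas <- prof$theta_deg
    } else pooled_acc <- pooled_acc + cbind(prof$length, prof$crossings)
  }
  capped <- pooled_acc[, 2] == 0
  pooled_prof <- structure(
    data.frame(theta_deg = pooled_thetas, length = pooled_acc[, 1],
               crossings = pooled_acc[, 2],
               mil = ifelse(capped, pooled_acc[, 1],
                            pooled_acc[, 1] / pmax(pooled_acc[, 2], 1)),
               capped = capped),
    class = c("mil_profile_2d", "data.frame"))
  alpha_specimen <- pto_2d(pooled_prof)
  list(id = entry$id, group = entry$group, sides = per_side,
       alpha = alpha_specimen)
}

#' Run a full study
#'
#' Analyses every specimen, assembles the per-VOI morphometry table and the
#' stereoplot coordinate table, and computes the group statistics: exact
#' rank-sum per scalar parameter and side, the 2D median permutation test on
#' the specimen-level alphas, and the 3D haversine-centroid permutation test
#' per side. `config$stats$pooled` entries of the form
#' `list(pool = c("A", "B"), versus = "C")` add pooled-group comparisons.
#'
#' @param config a `study_config` (list or from [read_study_config()]).
#' @param progress print per-specimen progress.
#' @return A `study_report`: `records`, `table` (Table-style data.frame),
#'   `stereo` (specimen, side, longitude, latitude, x, y), `stats` (ledger of
#'   every test), `provenance`.
#' @export
run_study <- function(config, progress = FALSE) {
  config <- validate_study_config(config)
  groups <- vapply(config$specimens, function(s) s$group, character(1))
  if (length(unique(groups)) < 2) stop("need >= 2 groups with >= 1 specimen")
  seed <- as.integer(config$stats$seed)

  records <- lapply(config$specimens, function(sp) {
    if (progress) message("specimen ", sp$id)
    run_specimen(sp, seed = seed)
  })

  table <- do.call(rbind, lapply(records, function(r) {
    do.call(rbind, lapply(r$sides, function(s) {
      df <- as.data.frame(s$morphometry)
      df$alpha_2d <- s$orientation_2d$alpha
      df
    }))
  }))
  table$group <- rep(vapply(records, `[[`, character(1), "group"),
                     each = 2L)
  rownames(table) <- NULL

  stereo <- do.call(rbind, lapply(records, function(r) {
    do.call(rbind, lapply(names(r$sides), function(side) {
      ll <- to_lonlat(r$sides[[side]]$fabric$pto)
      cbind(data.frame(specimen = r$id, side = side), ll,
            stereo_project(ll))
    }))
  }))
  rownames(stereo) <- NULL

  # ---- statistics ledger -------------------------------------------------
  alphas <- vapply(records, function(r) r$alpha$alpha, numeric(1))
  grp_of <- vapply(records, `[[`, character(1), "group")
  axes_by_side <- lapply(c("medial", "lateral"), function(side)
    t(vapply(records, function(r) r$sides[[side]]$fabric$pto, numeric(3))))
  names(axes_by_side) <- c("medial", "lateral")

  comparisons <- utils::combn(unique(grp_of), 2, simplify = FALSE)
  comparisons <- lapply(comparisons, function(p) list(pool = p[1], versus = p[2]))
  if (!is.null(config$stats$pooled))
    comparisons <- c(comparisons, config$stats$pooled)

  stats_ledger <- list()
  for (cmp in comparisons) {
    sel_a <- grp_of %in% unlist(cmp$pool)
    sel_b <- grp_of %in% unlist(cmp$versus)
    label <- paste(paste(unlist(cmp$pool), collapse = "+"), "vs",
                   paste(unlist(cmp$versus), collapse = "+"))
    if (sum(sel_a) < 1 || sum(sel_b) < 1) next
    if (sum(sel_a) == 1 && sum(sel_b) == 1)
      warning("singleton-vs-singleton permutation: p can only be 1 (", label, ")")
    entry <- list(comparison = label)
    entry$alpha_2d <- permutation_test_median(alphas[sel_a], alphas[sel_b],
                                              n_draws = config$stats$n_draws,
                                              seed = seed)
    if (sum(sel_a) >= 2 && sum(sel_b) >= 2) {
      for (side in c("medial", "lateral")) {
        entry[[paste0("pto3d_", side)]] <-
          permutation_test_sphere(axes_by_side[[side]][sel_a, , drop = FALSE],
                                  axes_by_side[[side]][sel_b, , drop = FALSE],
                                  axial = isTRUE(config$stats$axial),
                                  n_draws = config$stats$n_draws, seed = seed)
      }
    }
    for (param in c("bvtv_pct", "tb_n", "tb_th_mm", "tb_sp_mm", "da", "conn_d")) {
      for (side in c("medial", "lateral")) {
        va <- table[[param]][table$group %in% unlist(cmp$pool) & table$side == side]
        vb <- table[[param]][table$group %in% unlist(cmp$versus) & table$side == side]
        entry$rank_sum[[paste(param, side, sep = "_")]] <- exact_rank_sum(va, vb)
      }
    }
    stats_ledger[[label]] <- entry
  }

  structure(list(records = records, table = table, stereo = stereo,
                 stats = stats_ledger,
                 provenance = list(
                   version = as.character(utils::packageVersion("fabricgait")),
                   seed = seed,
                   config_hash = config_hash(config),
                   timestamp = NA)),
            class = "study_report")
}

# order-stable FNV-1a-style hash of the config's serialized form (no external
# digest dependency)
config_hash <- function(config) {
  # hash the scientific configuration only: in-memory volumes and file paths
  # are excluded so equal studies hash equally wherever they are run
  config$specimens <- lapply(config$specimens, function(s) {
    s$volume <- NULL; s$path <- NULL; s
  })
  s <- utils::capture.output(utils::str(config, vec.len = 1e6, digits.d = 15))
  bytes <- utf8ToInt(paste(s, collapse = "\n"))
  h <- 216613626
  for (b in bytes) h <- (bitwXor(h, b) * 16777619) %% 2^31
  sprintf("%08x", h)
}

#' Write study report files
#'
#' Emits `table1.csv` (one row per specimen per side in the canonical column
#' order), `stereoplot.csv` (specimen, side, longitude, latitude, x, y),
#' `stats.json` (machine-readable statistics ledger sufficient to replay every
#' reported p) and `log.txt`.
#'
#' @param report a `study_report`.
#' @param outdir output directory (created if needed).
#' @export
write_study_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  tab <- report$table[, c("id", "group", "side", "alpha_2d", "bvtv_pct",
                          "tb_n", "tb_th_mm", "tb_sp_mm", "da", "conn_d")]
  utils::write.csv(tab, file.path(outdir, "table1.csv"), row.names = FALSE)
  utils::write.csv(report$stereo, file.path(outdir, "stereoplot.csv"),
                   row.names = FALSE)
  ledger <- lapply(report$stats, function(entry) {
    out <- list(comparison = entry$comparison)
    for (nm in setdiff(names(entry), c("comparison", "rank_sum"))) {
      pr <- entry[[nm]]
      out[[nm]] <- list(statistic = pr$statistic, p_value = pr$p_value,
                        n_allocations = pr$n_allocations, mode = pr$mode,
                        n_degenerate = pr$n_degenerate)
    }
    out$rank_sum <- entry$rank_sum
    out
  })
  jsonlite::write_json(list(provenance = report$provenance, tests = ledger),
                       file.path(outdir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(c(sprintf("fabricgait %s", report$provenance$version),
               sprintf("seed %d, config %s", report$provenance$seed,
                       report$provenance$config_hash),
               sprintf("%d specimens, %d comparisons",
                       length(report$records), length(report$stats))),
             file.path(outdir, "log.txt"))
  invisible(outdir)
}

#' Demo study on generated data
#'
#' Generates a miniature three-group study — two "species" groups (n = 6
#' each) whose true sagittal PTO differs by 7.7 degrees, plus an n = 3
#' "fossil" group at the first species' orientation — writes the volumes as
#' TIFF stacks with config, runs [run_study()] end to end and writes all
#' reports.
#'
#' @param outdir writable output directory.
#' @param seed master seed.
#' @param size fixture edge length in voxels (default 96; the full-scale
#'   protocol corresponds to larger volumes, scaled down here for runtime).
#' @param n1,n2,n3 group sizes.
#' @param offset_deg true sagittal PTO offset of group 2 in degrees.
#' @return The `study_report`, invisibly; files in `outdir`.
#' @export
run_demo <- function(outdir, seed = 1L, size = 96L, n1 = 6L, n2 = 6L, n3 = 3L,
                     offset_deg = 7.7) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(as.integer(seed))
  tilt_axis <- function(delta_deg) {
    d <- delta_deg * pi / 180
    c(-sin(d), 0, cos(d)) # tilt in the sagittal (x-z) plane
  }
  groups <- list(species_a = list(n = n1, axis = tilt_axis(0)),
                 species_b = list(n = n2, axis = tilt_axis(offset_deg)),
                 fossil = list(n = n3, axis = tilt_axis(0)))
  half <- (size - 1) / 2
  d_or <- max(20L, as.integer(size * 0.4))
  d_mo <- max(24L, as.integer(size * 0.55))
  off <- size * 0.12
  specimens <- list()
  k <- 0L
  for (g in names(groups)) {
    for (i in seq_len(groups[[g]]$n)) {
      k <- k + 1L
      sp_seed <- as.integer((seed * 1000L + k) %% .Machine$integer.max)
      vol <- make_rod_lattice(rod_lattice_spec(
        shape = rep(size, 3), rod_radius = 1.6, spacing = 8,
        primary_axis = groups[[g]]$axis, secondary_fill = 0.25,
        jitter_sd = 0.9, seed = sp_seed))
      id <- sprintf("%s_%02d", g, i)
      path <- file.path(outdir, paste0(id, ".tif"))
      write_stack(vol, path)
      specimens[[k]] <- list(
        id = id, group = g, path = path, spacing_um = vol$spacing_um,
        vois = list(
          medial_orientation = list(center = c(half, half - off, half), diameter = d_or),
          lateral_orientation = list(center = c(half, half + off, half), diameter = d_or),
          medial_morphometry = list(center = c(half, half - off, half), diameter = d_mo),
          lateral_morphometry = list(center = c(half, half + off, half), diameter = d_mo)))
    }
  }
  config <- list(specimens = specimens,
                 stats = list(seed = as.integer(seed), n_draws = 1e4,
                              axial = TRUE,
                              pooled = list(list(pool = c("species_a", "fossil"),
                                                 versus = "species_b"))))
  write_study_config(config, file.path(outdir, "config.json"))
  report <- run_study(config)
  write_study_report(report, outdir)
  invisible(report)
}
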