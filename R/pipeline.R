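## End-to-end multi-temperature unfolding analysis: order-parameter time
## series, a per-temperature mean +/- SD summary table, free-energy
## landscapes for configured order-parameter pairs, start/end-window
## DCCMs, secondary-structure timelines and a tracked side-chain SASA vs
## RMSD scatter, written as plain-text outputs with a run log.

#' Configuration for an unfolding-analysis run
#'
#' Either supply `trajectories` (a named list of [md_trajectory()]
#' objects, or a character vector of multi-model PDB paths with
#' `temperatures`), or leave them NULL to analyse a synthetic thermal
#' ladder generated from `schedule` and the generator settings.
#'
#' @param trajectories named list of trajectories or PDB paths; NULL for
#'   a synthetic ladder.
#' @param temperatures temperature labels (K) for PDB paths.
#' @param schedule synthetic occupancy schedule (see [thermal_series()]).
#' @param n_residues,n_frames,jitter_sigma,dwell generator settings (see
#'   [synthetic_config()]).
#' @param native_reference native reference coordinates: NULL (frame 1 of
#'   the coldest trajectory), a frame index into it, or an
#'   `n_atoms x 3` matrix.
#' @param nc_cutoff,nc_min_sep native-contact definition (4 Angstrom, 3).
#' @param fel_pairs list of order-parameter name pairs for landscapes;
#'   names drawn from `rmsd`, `rg`, `nc`, `sasa`, `hbonds`.
#' @param fel_bins bins per FEL axis (default `c(60, 60)`).
#' @param dccm_edge_fraction fraction of frames in the start/end DCCM
#'   windows (default 0.1).
#' @param tracked_residue residue whose side-chain SASA is followed
#'   (default: the toy tryptophan for synthetic runs; otherwise none).
#' @param sasa_stride,ss_stride frame strides for the SASA series and the
#'   secondary-structure timeline (default 5; these are the two costly
#'   per-frame computations).
#' @param sasa_points Shrake-Rupley quadrature points (default 240).
#' @param discard_initial_fraction equilibration fraction discarded before
#'   the summary statistics (default 0).
#' @param out_dir output directory (created if needed).
#' @param seed master seed for the synthetic generator.
#' @return list of class `run_config`.
#' @export
run_config <- function(trajectories = NULL, temperatures = NULL,
                       schedule = NULL, n_residues = 30, n_frames = 1500,
                       jitter_sigma = 0.3, dwell = 5,
                       native_reference = NULL,
                       nc_cutoff = 4.0, nc_min_sep = 3,
                       fel_pairs = list(c("nc", "rmsd"), c("nc", "rg"),
                                        c("hbonds", "nc")),
                       fel_bins = c(60, 60), dccm_edge_fraction = 0.1,
                       tracked_residue = NULL, sasa_stride = 5,
                       ss_stride = 5, sasa_points = 240,
                       discard_initial_fraction = 0,
                       out_dir = tempfile("mdunfold_run_"), seed = 1) {
  structure(as.list(environment()), class = "run_config")
}

#' Read a flat key=value run-configuration file
#'
#' Lines of the form `key = value` (or `key=value`); `#` comments and
#' blank lines ignored.  Numeric-looking values are coerced.  Keys must
#' be [run_config()] argument names.
#'
#' @param path configuration file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2
  if (any(bad)) stop("unparseable config line: ", lines[which(bad)[1]])
  keys <- vapply(kv, `[`, character(1), 1)
  vals <- lapply(kv, function(x) {
    v <- x[2]
    num <- suppressWarnings(as.numeric(strsplit(v, "\\s+")[[1]]))
    if (!anyNA(num)) num else v
  })
  names(vals) <- keys
  unknown <- setdiff(keys, names(formals(run_config)))
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  do.call(run_config, vals)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full multi-temperature unfolding analysis
#'
#' Produces, under `config$out_dir`: per-temperature series CSVs (RMSD and
#' Rg in nm, Nc fraction, total SASA in nm^2, intraprotein H-bond count,
#' tracked side-chain SASA in Angstrom^2), a per-temperature mean +/- SD
#' summary table, free-energy grids for the configured order-parameter
#' pairs, DCCMs for the start and end windows, secondary-structure
#' timelines, a side-chain-SASA-vs-RMSD scatter table, hidden-state ground
#' truth for synthetic inputs, a run log recording every defaulted
#' parameter, and a `COMPLETE` marker written only when every stage
#' succeeded.  The run is deterministic given the config and seed.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with `summary` (the summary table),
#'   `out_dir`, `trajectories`, and `fel_grids`.
#' @export
run_unfolding_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  log_con <- file(log_path, "w")
  on.exit(close(log_con), add = TRUE)
  logmsg <- function(level, fmt, ...) {
    writeLines(sprintf("[%s] %s", level, sprintf(fmt, ...)), log_con)
  }
  defaults_used <- setdiff(names(formals(run_config)), "out_dir")
  for (nm in defaults_used) {
    logmsg("WARN", "parameter '%s' = %s", nm,
           paste(utils::capture.output(dput(config[[nm]]))[1], collapse = ""))
  }

  trajs <- .stage("input", {
    if (is.null(config$trajectories)) {
      sc <- synthetic_config(n_residues = config$n_residues,
                             n_frames = config$n_frames,
                             jitter_sigma = config$jitter_sigma,
                             dwell = config$dwell, seed = config$seed)
      thermal_series(sc, schedule = config$schedule)
    } else if (is.character(config$trajectories)) {
      if (is.null(config$temperatures) ||
          length(config$temperatures) != length(config$trajectories)) {
        stop("PDB inputs need one temperature label per file")
      }
      out <- Map(read_multimodel_pdb, config$trajectories,
                 temperature = config$temperatures)
      names(out) <- paste0(config$temperatures, "K")
      out
    } else config$trajectories
  })
  temps <- vapply(trajs, function(t) t$temperature, numeric(1))
  ord <- order(temps)
  trajs <- trajs[ord]; temps <- temps[ord]
  logmsg("INFO", "analysing %d trajectories at %s K", length(trajs),
         paste(temps, collapse = ", "))

  coldest <- trajs[[1]]
  native_ref <- .stage("native reference", {
    nr <- config$native_reference
    if (is.null(nr)) {
      # synthetic runs carry their noise-free native template; real inputs
      # fall back to the first frame of the coldest trajectory
      tmpl <- attr(coldest, "native_template")
      if (!is.null(tmpl)) {
        logmsg("INFO", "native reference: generator's native template")
        tmpl
      } else {
        logmsg("WARN", "native reference defaulted to frame 1 of %s",
               names(trajs)[1])
        frame_coords(coldest, 1)
      }
    } else if (is.matrix(nr)) nr
    else frame_coords(coldest, nr)
  })
  native <- .stage("native contacts", {
    native_contacts(coldest, reference_frame = native_ref,
                    cutoff = config$nc_cutoff,
                    min_sequence_separation = config$nc_min_sep)
  })
  logmsg("INFO", "native contact set: %d pairs", native$n_pairs)

  tracked <- config$tracked_residue
  if (is.null(tracked)) {
    sc_counts <- tapply(coldest$model$atoms$is_sidechain,
                        coldest$model$atoms$res_index, sum)
    tracked <- if (max(sc_counts) >= 5) as.integer(which.max(sc_counts))
               else NA_integer_
    logmsg("WARN", "tracked_residue defaulted to %s", tracked)
  }

  summary_rows <- list()
  fel_grids <- list()
  all_series <- list()
  for (k in seq_along(trajs)) {
    tr <- trajs[[k]]
    tl <- names(trajs)[k]
    series <- .stage(paste0("order parameters ", tl), {
      list(rmsd = rmsd_series(tr, reference = native_ref),
           rg = radius_of_gyration_series(tr),
           nc = nc_fraction_series(tr, native),
           sasa = sasa_series(tr, n_sphere_points = config$sasa_points,
                              stride = config$sasa_stride),
           hbonds = hbond_count_series(tr))
    })
    if (!is.na(tracked)) {
      series$sidechain_sasa <- .stage(paste0("side-chain SASA ", tl), {
        residue_sidechain_sasa_series(tr, tracked,
                                      n_sphere_points = config$sasa_points,
                                      stride = config$sasa_stride)
      })
    }
    # unit conversion at reporting: A -> nm, A^2 -> nm^2 (tracked
    # side-chain SASA stays in A^2)
    rep_series <- series
    rep_series$rmsd$values <- series$rmsd$values / 10
    rep_series$rmsd$units <- "nm"
    rep_series$rg$values <- series$rg$values / 10
    rep_series$rg$units <- "nm"
    rep_series$sasa$values <- series$sasa$values / 100
    rep_series$sasa$units <- "nm^2"
    for (nm in names(rep_series)) {
      write_series_csv(rep_series[[nm]],
                       file.path(config$out_dir,
                                 sprintf("%s_%s.csv", nm, tl)))
    }
    all_series[[tl]] <- series

    stats <- lapply(rep_series[c("rmsd", "rg", "nc", "sasa")],
                    summarize_series,
                    discard_initial_fraction = config$discard_initial_fraction)
    summary_rows[[tl]] <- data.frame(
      temperature_K = tr$temperature,
      rmsd_nm_mean = stats$rmsd["mean"], rmsd_nm_sd = stats$rmsd["sd"],
      rg_nm_mean = stats$rg["mean"], rg_nm_sd = stats$rg["sd"],
      nc_mean = stats$nc["mean"], nc_sd = stats$nc["sd"],
      sasa_nm2_mean = stats$sasa["mean"], sasa_nm2_sd = stats$sasa["sd"],
      row.names = NULL)

    for (pair in config$fel_pairs) {
      grid <- .stage(sprintf("FEL %s vs %s %s", pair[1], pair[2], tl), {
        sx <- series[[pair[1]]]; sy <- series[[pair[2]]]
        if (is.null(sx) || is.null(sy)) {
          stop("unknown order-parameter name in fel_pairs")
        }
        if (length(sx$values) != length(sy$values)) {
          stop(sprintf("series '%s' and '%s' have different strides",
                       pair[1], pair[2]))
        }
        fel_2d(sx, sy, n_bins = config$fel_bins,
               temperature = tr$temperature)
      })
      key <- sprintf("fel_%s_%s_%s", pair[1], pair[2], tl)
      fel_grids[[key]] <- grid
      write_fel_grid(grid, file.path(config$out_dir,
                                     paste0(key, ".txt")))
    }

    .stage(paste0("DCCM ", tl), {
      wins <- dccm_windows(tr, edge_fraction = config$dccm_edge_fraction)
      for (wn in names(wins)) {
        write_dccm_csv(wins[[wn]],
                       file.path(config$out_dir,
                                 sprintf("dccm_%s_frames%s.csv", tl, wn)))
      }
    })

    .stage(paste0("secondary structure ", tl), {
      timeline <- ss_timeline(tr, stride = config$ss_stride)
      write_ss_timeline_csv(timeline,
                            file.path(config$out_dir,
                                      sprintf("ss_timeline_%s.csv", tl)))
      write.csv(ss_content_series(timeline),
                file.path(config$out_dir,
                          sprintf("ss_content_%s.csv", tl)),
                row.names = FALSE, quote = FALSE)
    })

    if (!is.na(tracked)) {
      .stage(paste0("SASA-RMSD scatter ", tl), {
        sub <- match(series$sidechain_sasa$times, series$rmsd$times)
        write.csv(data.frame(
          time_ps = series$sidechain_sasa$times,
          rmsd_nm = series$rmsd$values[sub] / 10,
          sidechain_sasa_A2 = series$sidechain_sasa$values),
          file.path(config$out_dir,
                    sprintf("sidechain_sasa_vs_rmsd_%s.csv", tl)),
          row.names = FALSE, quote = FALSE)
      })
    }

    if (!is.null(attr(tr, "state_path"))) {
      write_ground_truth_csv(tr,
        file.path(config$out_dir, sprintf("ground_truth_%s.csv", tl)))
    }
  }

  summary_tab <- do.call(rbind, summary_rows)
  rownames(summary_tab) <- NULL
  sfile <- file.path(config$out_dir, "summary_table.csv")
  con <- file(sfile, "w")
  writeLines(paste(names(summary_tab), collapse = ","), con)
  for (i in seq_len(nrow(summary_tab))) {
    writeLines(paste(.fmt_num(as.numeric(summary_tab[i, ])),
                     collapse = ","), con)
  }
  close(con)
  logmsg("INFO", "summary table written: %s", basename(sfile))
  writeLines("run completed", file.path(config$out_dir, "COMPLETE"))
  invisible(list(summary = summary_tab, out_dir = config$out_dir,
                 trajectories = trajs, fel_grids = fel_grids,
                 tracked_residue = tracked))
}
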