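#' Read a pipeline run configuration
#'
#' Configurations are single human-readable YAML or JSON files. See
#' [run_pipeline()] for the schema.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON (`.json`) file.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
}

pipeline_stage_names <- c("simulate", "segment", "detect", "enrich",
                          "compare", "coloc", "ripq")

validate_config <- function(config) {
  known <- c("seed", "out", "stages", pipeline_stage_names, "scene_defaults")
  bad <- setdiff(names(config), known)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "),
         " (known: ", paste(known, collapse = ", "), ")")
  stages <- config$stages
  if (is.null(stages)) stop("config must list the stages to run")
  bad <- setdiff(stages, pipeline_stage_names)
  if (length(bad))
    stop("unknown stages: ", paste(bad, collapse = ", "))
  stages
}

#' Run an end-to-end synthetic analysis pipeline
#'
#' Glues the package stages — simulate, segment, detect, enrich, compare,
#' coloc, ripq — into one reproducible run. Each stage writes its outputs
#' (TIFF stacks, CSV tables) under `out/<condition>/` and later stages read
#' those files back, so any stage can be replayed from the files of the
#' preceding one. A machine-readable JSON report (parameters echo, output
#' file hashes, collected warnings) is written to `out/report.json`.
#' Identical configuration and seed produce byte-identical CSV outputs.
#'
#' Config schema (YAML or JSON; all stage blocks optional except those named
#' in `stages`):
#' \preformatted{
#' seed: 7
#' stages: [simulate, detect, enrich, compare]
#' simulate:
#'   conditions:
#'     - {name: high, r: 2, n_cells: 8}
#'     - {name: null_r1, r: 1, n_cells: 8}
#' scene_defaults: {spots_per_cell: 60}   # merged into every condition
#' segment: {min_area: 50, smooth_sigma: 2}
#' detect: {sigma_xy: 1.3, sigma_z: 1.0, threshold: 60}
#' enrich: {min_spots: 5, norm: median}
#' compare: [[high, null_r1]]
#' coloc: {d_max: 300, n_perm: 0}
#' ripq: {statistic: percent_input}      # plus cp_sim_params fields or table:
#' }
#'
#' When `segment` (or `detect`) is not among the stages, downstream stages
#' fall back to the simulated ground-truth masks (or spot tables).
#'
#' @param config configuration list or path to a YAML/JSON file.
#' @param out output directory (overrides `config$out`).
#' @param seed global seed (overrides `config$seed`); per-condition streams
#'   are derived from it deterministically.
#' @return The run report, invisibly (also written as JSON).
#' @export
run_pipeline <- function(config, out = NULL, seed = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stages <- validate_config(config)
  out <- out %||% config$out %||% stop("no output directory given")
  seed <- as.integer(seed %||% config$seed %||% 1L)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  report <- list(seed = seed, stages = list(), warnings = character())
  note_warn <- function(w) {
    report$warnings <<- c(report$warnings, conditionMessage(w))
    invokeRestart("muffleWarning")
  }
  run_stage <- function(name, code) {
    t0 <- Sys.time()
    res <- withCallingHandlers(code, warning = note_warn)
    report$stages[[name]] <<- c(res, list(
      elapsed_s = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 2)))
    res
  }

  conditions <- config$simulate$conditions
  if (is.data.frame(conditions))
    conditions <- lapply(seq_len(nrow(conditions)),
                         function(i) as.list(conditions[i, ]))
  cond_names <- vapply(conditions, function(cc) cc$name %||% "scene",
                       character(1))

  if ("simulate" %in% stages) {
    run_stage("simulate", {
      outputs <- character()
      for (i in seq_along(conditions)) {
        cc <- conditions[[i]]
        pars <- utils::modifyList(config$scene_defaults %||% list(),
                                  cc[setdiff(names(cc), "name")])
        pars$seed <- seed + i
        if (!is.null(pars$shape)) {
          pars$shape <- unlist(pars$shape)
          if (is.null(names(pars$shape))) names(pars$shape) <- c("z", "y", "x")
        }
        sp <- do.call(scene_params, pars)
        scene <- simulate_scene(sp)
        cdir <- file.path(out, cond_names[i])
        paths <- write_scene(scene, cdir)
        stacks <- render_stacks(scene)
        for (ch in names(stacks)) {
          f <- file.path(cdir, paste0(ch, ".tif"))
          write_stack(stacks[[ch]], f)
          outputs <- c(outputs, f)
        }
        outputs <- c(outputs, paths)
      }
      list(conditions = cond_names, outputs = hash_files(outputs),
           params_echo = config$simulate)
    })
  }

  geom_for <- function(name) {
    cdir <- file.path(out, name)
    if ("segment" %in% stages &&
        file.exists(file.path(cdir, "seg_cells.tif")))
      load_geometry(file.path(cdir, "seg_cells.tif"),
                    file.path(cdir, "seg_nuclei.tif"))
    else load_geometry(file.path(cdir, "cells_mask.tif"),
                       file.path(cdir, "nuclei_mask.tif"))
  }
  scene_pars <- function(name) {
    jsonlite::read_json(file.path(out, name, "scene_params.json"),
                        simplifyVector = TRUE)
  }
  stack_for <- function(name, ch) {
    sp <- scene_pars(name)
    read_stack(file.path(out, name, paste0(ch, ".tif")),
               voxel_xy = sp$voxel_xy, voxel_z = sp$voxel_z,
               bit_depth = sp$bit_depth)
  }
  spots_for <- function(name, ch) {
    cdir <- file.path(out, name)
    sp <- scene_pars(name)
    f_det <- file.path(cdir, paste0("spots_", ch, ".csv"))
    s <- if ("detect" %in% stages && file.exists(f_det)) read_spots(f_det)
         else read_spots(file.path(cdir, "true_spots.csv"), channel = ch)
    s$settings$voxel_xy <- sp$voxel_xy
    s
  }

  if ("segment" %in% stages) {
    run_stage("segment", {
      pars <- config$segment %||% list()
      outputs <- character()
      for (name in cond_names) {
        cdir <- file.path(out, name)
        # mask estimation works on mean projections (noise suppression);
        # the focus projection is exposed for spot-preserving 2D views
        nuclei <- segment_nuclei(mean_projection(stack_for(name, "dapi")),
                                 min_area = pars$min_area %||% 50L)
        cells <- segment_cells(mean_projection(stack_for(name, "fish_a")),
                               nuclei,
                               smooth_sigma = pars$smooth_sigma %||% 2)
        f1 <- file.path(cdir, "seg_nuclei.tif")
        f2 <- file.path(cdir, "seg_cells.tif")
        write_label_mask(nuclei, f1)
        write_label_mask(cells, f2)
        geom <- cell_geometry(cells, nuclei)
        f3 <- file.path(cdir, "geometry_report.csv")
        utils::write.csv(geom$report, f3, row.names = FALSE)
        outputs <- c(outputs, f1, f2, f3)
      }
      list(outputs = hash_files(outputs), params_echo = pars)
    })
  }

  if ("detect" %in% stages) {
    run_stage("detect", {
      pars <- config$detect %||% list()
      outputs <- character()
      for (name in cond_names) {
        sp <- scene_pars(name)
        chans <- intersect(c("fish_a", "fish_b"),
                           vapply(list.files(file.path(out, name),
                                             pattern = "^fish_.\\.tif$"),
                                  function(f) sub("\\.tif$", "", f),
                                  character(1)))
        for (ch in chans) {
          spots <- detect_spots(stack_for(name, ch),
                                sigma_xy = pars$sigma_xy %||% 1.3,
                                sigma_z = pars$sigma_z %||% 1.0,
                                threshold = pars$threshold %||% 0,
                                channel = ch)
          f <- file.path(out, name, paste0("spots_", ch, ".csv"))
          write_spots(spots, f)
          outputs <- c(outputs, f)
        }
      }
      list(outputs = hash_files(outputs), params_echo = pars)
    })
  }

  ratios <- list()
  if ("enrich" %in% stages) {
    run_stage("enrich", {
      pars <- config$enrich %||% list()
      outputs <- character()
      summaries <- list()
      for (name in cond_names) {
        geom <- geom_for(name)
        tab <- enrichment_table(stack_for(name, "if"),
                                spots_for(name, "fish_a"), geom,
                                min_spots = pars$min_spots %||% 5L,
                                norm = pars$norm %||% "median")
        f <- file.path(out, name, "enrichment.csv")
        utils::write.csv(tab, f, row.names = FALSE)
        outputs <- c(outputs, f)
        ratios[[name]] <- tab$ratio[!is.na(tab$ratio)]
        if (sum(!is.na(tab$ratio)) >= 2) {
          s <- summarize_condition(tab$ratio, name)
          summaries[[name]] <- data.frame(
            condition = name, n = s$n, mean = s$mean, sd = s$sd,
            ci_lo = s$ci[1], ci_hi = s$ci[2])
        }
      }
      f <- file.path(out, "condition_summary.csv")
      utils::write.csv(do.call(rbind, summaries), f, row.names = FALSE)
      list(outputs = hash_files(c(outputs, f)), params_echo = pars)
    })
  }

  if ("compare" %in% stages) {
    run_stage("compare", {
      if (!length(ratios))
        stop("the compare stage needs per-cell ratios: run the enrich stage")
      pairs <- config$compare
      if (is.null(pairs)) pairs <- list(cond_names[1:2])
      rows <- lapply(pairs, function(p) {
        ks <- compare_ks(ratios[[p[[1]]]], ratios[[p[[2]]]])
        data.frame(condition_a = p[[1]], condition_b = p[[2]],
                   n_a = length(ratios[[p[[1]]]]),
                   n_b = length(ratios[[p[[2]]]]),
                   D = ks$statistic, p_value = ks$p.value)
      })
      tab <- do.call(rbind, rows)
      f <- file.path(out, "ks_comparisons.csv")
      utils::write.csv(tab, f, row.names = FALSE)
      list(outputs = hash_files(f), comparisons = tab)
    })
  }

  if ("coloc" %in% stages) {
    run_stage("coloc", {
      pars <- config$coloc %||% list()
      d_max <- pars$d_max %||% 300
      n_perm <- pars$n_perm %||% 0L
      outputs <- character()
      for (name in cond_names) {
        geom <- geom_for(name)
        sa <- spots_for(name, "fish_a")
        sb <- spots_for(name, "fish_b")
        sp <- scene_pars(name)
        rows <- lapply(geom$labels, function(l) {
          ca <- filter_spots(sa, geom, l)
          cb <- filter_spots(sb, geom, l)
          if (n_spots(ca) == 0 || n_spots(cb) == 0) return(NULL)
          m <- match_clouds(ca, cb, d_max)
          row <- data.frame(cell_id = l, n_a = m$n_a, n_b = m$n_b,
                            n_pairs = nrow(m$pairs),
                            fraction = coloc_fraction(m, "a"),
                            d_max = d_max, p_null = NA_real_)
          if (n_perm >= 100) {
            nl <- randomization_null(ca, cb, geom, l, d_max = d_max,
                                     n_perm = n_perm, seed = seed + 100 + l,
                                     voxel_xy = sp$voxel_xy)
            row$p_null <- nl$p.value
          }
          row
        })
        f <- file.path(out, name, "coloc_fractions.csv")
        utils::write.csv(do.call(rbind, rows), f, row.names = FALSE)
        outputs <- c(outputs, f)
      }
      list(outputs = hash_files(outputs), params_echo = pars)
    })
  }

  if ("ripq" %in% stages) {
    run_stage("ripq", {
      pars <- config$ripq %||% list()
      tab <- if (!is.null(pars$table)) read_cp_table(pars$table)
      else {
        sim_args <- pars[intersect(names(pars),
                                   names(formals(cp_sim_params)))]
        if (!is.null(sim_args$abundances))
          sim_args$abundances <- unlist(sim_args$abundances)
        if (is.null(sim_args$seed)) sim_args$seed <- seed + 7L
        simulate_cp_table(do.call(cp_sim_params, sim_args))
      }
      f1 <- file.path(out, "cp_table.csv")
      write_cp_table(tab, f1)
      agg <- aggregate_replicates(
        tab, statistic = pars$statistic %||% "percent_input",
        reference_gene = pars$reference_gene,
        input_correction = pars$input_correction %||% 6.644)
      f2 <- file.path(out, "enrichment_records.csv")
      utils::write.csv(agg$summary, f2, row.names = FALSE)
      list(outputs = hash_files(c(f1, f2)), params_echo = pars,
           summary = agg$summary)
    })
  }

  report$config_echo <- config
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       pretty = TRUE)
  invisible(report)
}

hash_files <- function(paths) {
  h <- tools::md5sum(paths)
  data.frame(file = basename(names(h)), md5 = unname(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
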