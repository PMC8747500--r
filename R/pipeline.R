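# Pipeline wiring and command-line entry point. Subcommands: simulate,
# cluster, capillary, couple, leakage, compare, pipeline. Every run writes
# its resolved configuration (defaults included) beside the outputs, so no
# parameter is silent.

.default_run_config <- function() {
  list(threshold_nm = 70, min_points = 3L, pairing_nm = 100,
       band_nm = c(100, 300), diameter_method = "ellipse",
       normalize_by = "diameter", primary_channel = "claudin5",
       partner_channel = "zo1", tracer_channel = "tracer",
       reference_group = NULL, seed = 1L, out_dir = ".")
}

#' Resolve a pipeline run configuration
#'
#' Fills unset fields with the package defaults (clustering threshold 70 nm,
#' minimum cluster size 3, coupling distance 100 nm, abluminal band
#' 100-300 nm, matched-ellipse diameter).
#'
#' @param ... Named overrides, or a single list of them.
#' @return A `run_config` list.
#' @export
run_config <- function(...) {
  over <- list(...)
  if (length(over) == 1L && is.null(names(over)) && is.list(over[[1]]))
    over <- over[[1]]
  cfg <- .default_run_config()
  unknown <- setdiff(names(over),
                     c(names(cfg), "capillaries"))
  if (length(unknown))
    stop_tj("unknown config fields: ", paste(unknown, collapse = ", "),
            class = "tjstorm_config_error")
  cfg[names(over)] <- over
  if (cfg$threshold_nm <= 0 || cfg$min_points < 1 || cfg$pairing_nm <= 0 ||
      length(cfg$band_nm) != 2 || cfg$band_nm[1] < 0 ||
      cfg$band_nm[2] <= cfg$band_nm[1])
    stop_tj("invalid run configuration values", class = "tjstorm_config_error")
  structure(cfg, class = "run_config")
}

.write_resolved_config <- function(cfg, out_dir) {
  keep <- cfg[!vapply(cfg, is.function, logical(1))]
  keep$capillaries <- lapply(keep$capillaries, function(cp)
    cp[vapply(cp, function(v) is.character(v) || is.numeric(v), logical(1))])
  jsonlite::write_json(keep, file.path(out_dir, "resolved_config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
}

.log_line <- function(con, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
  message(msg)
  if (!is.null(con)) writeLines(msg, con)
}

#' Run the full analysis pipeline
#'
#' Executes io -> clustering -> capillary/coupling -> leakage -> stats over
#' a set of capillaries and writes CSV/JSON outputs plus a log. Each
#' capillary is described by a list with `id`, `group`, `channels` (named
#' list, channel label -> molecular-list CSV path) and optionally `roi`
#' (ROI JSON path; when absent the ring is auto-fit as the convex hull of
#' the primary channel).
#'
#' @param config A [run_config()] with a `capillaries` field.
#' @return Invisible list with the collected tables (`clusters`,
#'   `capillaries`, `coupling`, `leakage`, `comparisons`).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  caps <- config$capillaries
  if (!length(caps))
    stop_tj("config$capillaries is empty", class = "tjstorm_config_error")
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file(file.path(out_dir, "run.log"), open = "wt")
  on.exit(close(logf))
  .log_line(logf, "tjstorm ", as.character(utils::packageVersion("tjstorm")),
            " | threshold ", config$threshold_nm, " nm | min_points ",
            config$min_points, " | pairing ", config$pairing_nm,
            " nm | band ", config$band_nm[1], "-", config$band_nm[2], " nm")

  cluster_rows <- list(); cap_rows <- list(); couple_rows <- list()
  leak_rows <- list(); dens_groups <- list()
  for (cp in caps) {
    id <- cp$id %||% "capillary"
    group <- cp$group %||% "group"
    chans <- lapply(names(cp$channels), function(nm) {
      p <- cp$channels[[nm]]
      if (!file.exists(p))
        stop_tj("stage io, capillary ", id, ": input file not found: ", p,
                class = "tjstorm_io_error")
      read_molecular_list(p, channel_label = nm)
    })
    names(chans) <- names(cp$channels)
    primary <- chans[[config$primary_channel]]
    if (is.null(primary))
      stop_tj("stage io, capillary ", id, ": no '",
              config$primary_channel, "' channel", class = "tjstorm_config_error")
    roi <- if (!is.null(cp$roi)) read_roi(cp$roi)
      else ring_from_localizations(primary, label = id)

    part <- partition_localizations(primary, config$threshold_nm)
    props <- compute_cluster_properties(primary, part, config$min_points)
    .log_line(logf, "capillary ", id, ": ", nrow(primary), " localizations, ",
              part$n_clusters, " clusters (", nrow(props), " with >= ",
              config$min_points, " points, ", sum(props$degenerate),
              " degenerate excluded from densities)")
    ct <- cluster_table(props)
    if (nrow(ct)) {
      ct$capillary_id <- id; ct$group <- group
      cluster_rows[[id]] <- ct
      d <- ct$density_per_um2[!ct$degenerate]
      dens_groups[[group]] <- c(dens_groups[[group]], d)
    }
    cap_rows[[id]] <- cbind(
      capillary_metrics(primary, roi, props, capillary_id = id,
                        diameter_method = config$diameter_method,
                        normalize_by = config$normalize_by),
      group = group)

    partner <- chans[[config$partner_channel]]
    if (!is.null(partner)) {
      ppart <- partition_localizations(partner, config$threshold_nm)
      pprops <- compute_cluster_properties(partner, ppart, config$min_points)
      cl <- pair_clusters(props, pprops, config$pairing_nm)
      if (nrow(cl)) {
        cl$capillary_id <- id; cl$group <- group
        couple_rows[[id]] <- cl
      }
    }

    tracer <- chans[[config$tracer_channel]]
    if (!is.null(tracer)) {
      band <- build_abluminal_band(roi, config$band_nm[1], config$band_nm[2])
      leak_rows[[id]] <- leakage_density(tracer, band, capillary_id = id,
                                         group = group)
    }
  }

  clusters <- do.call(rbind, unname(cluster_rows))
  capillaries <- do.call(rbind, unname(cap_rows))
  coupling <- if (length(couple_rows)) do.call(rbind, unname(couple_rows))
  leakage <- if (length(leak_rows)) do.call(rbind, unname(leak_rows))
  if (!is.null(leakage) && !is.null(config$reference_group)) {
    leakage <- relative_leakage_index(leakage, config$reference_group)
    .log_line(logf, "leakage index normalized to group '",
              config$reference_group, "' (mean density ",
              format(attr(leakage, "reference_mean_density")), " /um^2)")
  }

  comparisons <- NULL
  value_groups <- if (!is.null(leakage) && !all(is.na(leakage$relative_index)))
    split(leakage$relative_index, leakage$group) else dens_groups
  if (length(value_groups) == 2L) {
    mw <- mann_whitney_u(value_groups[[1]], value_groups[[2]])
    comparisons <- data.frame(test = mw$test,
                              group_a = names(value_groups)[1],
                              group_b = names(value_groups)[2],
                              statistic = mw$statistic, p_value = mw$p_value,
                              p_adjusted = NA_real_, method = mw$method)
  } else if (length(value_groups) >= 3L) {
    kw <- kruskal_wallis_dunn(value_groups)
    comparisons <- rbind(
      data.frame(test = "Kruskal-Wallis", group_a = "all", group_b = "all",
                 statistic = kw$omnibus$statistic,
                 p_value = kw$omnibus$p_value, p_adjusted = NA_real_,
                 method = "chi-squared"),
      data.frame(test = paste0("Dunn (", kw$p_adjust, ")"),
                 group_a = kw$pairwise$group_a, group_b = kw$pairwise$group_b,
                 statistic = kw$pairwise$z, p_value = kw$pairwise$p_value,
                 p_adjusted = kw$pairwise$p_adjusted, method = "z"))
  }

  wcsv <- function(df, name) if (!is.null(df) && nrow(df))
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  wcsv(clusters, "clusters.csv")
  wcsv(capillaries, "capillary_metrics.csv")
  wcsv(coupling, "coupling.csv")
  wcsv(leakage, "leakage.csv")
  wcsv(comparisons, "comparisons.csv")
  .write_resolved_config(config, out_dir)
  .log_line(logf, "done: outputs in ", normalizePath(out_dir))
  invisible(list(clusters = clusters, capillaries = capillaries,
                 coupling = coupling, leakage = leakage,
                 comparisons = comparisons, config = config))
}

# --- minimal subcommand argument parser ------------------------------------

.parse_flags <- function(args) {
  out <- list(); i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (!startsWith(a, "--"))
      stop_tj("unexpected argument '", a, "'", class = "tjstorm_cli_error")
    key <- gsub("-", "_", substring(a, 3))
    if (i == length(args) || startsWith(args[[i + 1L]], "--")) {
      out[[key]] <- TRUE; i <- i + 1L
    } else {
      out[[key]] <- args[[i + 1L]]; i <- i + 2L
    }
  }
  out
}

.flag_num <- function(flags, key, default) {
  if (is.null(flags[[key]])) return(default)
  as.numeric(flags[[key]])
}

.parse_band <- function(s, default = c(100, 300)) {
  if (is.null(s)) return(default)
  v <- as.numeric(strsplit(s, "[:,]")[[1]])
  if (length(v) != 2) stop_tj("--band-nm expects inner:outer",
                              class = "tjstorm_cli_error")
  v
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a synthetic scene), `cluster` (partition a
#' molecular list and export cluster properties), `capillary` (per-capillary
#' metrics), `couple` (cluster coupling between two channels), `leakage`
#' (abluminal band density and relative index over a manifest), `compare`
#' (group comparison on a CSV column), `pipeline` (full run from a JSON
#' config). Run with no arguments for usage. Invoke via
#' `Rscript -e 'tjstorm::cli_main()' <subcommand> ...` or the installed
#' `inst/cli/tjstorm` script.
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit status (0 on success), invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: tjstorm <subcommand> [--flags]",
    "  simulate  --preset P9|E12|occludin --seed N --out DIR",
    "            [--n-capillaries N] [--tracer-luminal D --tracer-abluminal D]",
    "  cluster   --in LIST.csv --out DIR [--threshold-nm 70] [--min-points 3]",
    "  capillary --in LIST.csv --roi ROI.json --out DIR [--threshold-nm 70]",
    "  couple    --primary LIST.csv --partner LIST.csv --out DIR",
    "            [--threshold-nm 70] [--pairing-nm 100]",
    "  leakage   --manifest MANIFEST.csv --reference-group G --out DIR",
    "            [--band-nm 100:300]   (manifest: capillary_id,group,tracer,roi)",
    "  compare   --in TABLE.csv --value-col COL --group-col COL --out DIR",
    "  pipeline  --config CONFIG.json",
    sep = "\n")
  status <- tryCatch({
    if (!length(args)) { message(usage); return(invisible(2L)) }
    cmd <- args[[1]]
    flags <- .parse_flags(args[-1])
    out_dir <- flags$out %||% "."
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    switch(cmd,
      simulate = {
        n_cap <- as.integer(flags$n_capillaries %||% 1L)
        seed <- as.integer(flags$seed %||% 1L)
        tracer <- if (!is.null(flags$tracer_luminal) ||
                      !is.null(flags$tracer_abluminal))
          list(luminal_density_um2 = .flag_num(flags, "tracer_luminal", 0),
               abluminal_density_um2 = .flag_num(flags, "tracer_abluminal", 0))
        for (i in seq_len(n_cap)) {
          cfg <- scene_preset(flags$preset %||% "P9", seed = seed + i - 1L,
                              tracer = tracer)
          write_scene(generate_scene(cfg),
                      file.path(out_dir, sprintf("capillary_%03d", i)))
        }
      },
      cluster = {
        tab <- read_molecular_list(flags$`in`)
        part <- partition_localizations(tab, .flag_num(flags, "threshold_nm", 70))
        props <- compute_cluster_properties(
          tab, part, as.integer(.flag_num(flags, "min_points", 3)))
        utils::write.csv(cluster_table(props),
                         file.path(out_dir, "clusters.csv"), row.names = FALSE)
        utils::write.csv(cbind(as.data.frame(tab),
                               cluster_id = part$assignment),
                         file.path(out_dir, "partition.csv"), row.names = FALSE)
        s <- cluster_summary(props)
        jsonlite::write_json(
          list(threshold_nm = part$threshold_nm, n_clusters = s$n_clusters,
               mean_density_per_um2 = s$mean_density,
               se_density = s$se_density, n_degenerate = s$n_degenerate),
          file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA,
          na = "null")
      },
      capillary = {
        tab <- read_molecular_list(flags$`in`)
        roi <- read_roi(flags$roi)
        part <- partition_localizations(tab, .flag_num(flags, "threshold_nm", 70))
        props <- compute_cluster_properties(
          tab, part, as.integer(.flag_num(flags, "min_points", 3)))
        utils::write.csv(capillary_metrics(tab, roi, props),
                         file.path(out_dir, "capillary_metrics.csv"),
                         row.names = FALSE)
      },
      couple = {
        t_nm <- .flag_num(flags, "threshold_nm", 70)
        mp <- as.integer(.flag_num(flags, "min_points", 3))
        pr <- read_molecular_list(flags$primary)
        pa <- read_molecular_list(flags$partner)
        props_pr <- compute_cluster_properties(
          pr, partition_localizations(pr, t_nm), mp)
        props_pa <- compute_cluster_properties(
          pa, partition_localizations(pa, t_nm), mp)
        labels <- pair_clusters(props_pr, props_pa,
                                .flag_num(flags, "pairing_nm", 100))
        utils::write.csv(labels, file.path(out_dir, "coupling.csv"),
                         row.names = FALSE)
        contrast <- coupling_density_contrast(labels, props_pr)
        jsonlite::write_json(contrast, file.path(out_dir, "coupling_summary.json"),
                             auto_unbox = TRUE, digits = NA, na = "null")
      },
      leakage = {
        man <- utils::read.csv(flags$manifest, stringsAsFactors = FALSE)
        band_nm <- .parse_band(flags$band_nm)
        rows <- lapply(seq_len(nrow(man)), function(i) {
          leakage_density(
            read_molecular_list(man$tracer[i], channel_label = "tracer"),
            build_abluminal_band(read_roi(man$roi[i]), band_nm[1], band_nm[2]),
            capillary_id = man$capillary_id[i], group = man$group[i])
        })
        leak <- do.call(rbind, rows)
        if (!is.null(flags$reference_group))
          leak <- relative_leakage_index(leak, flags$reference_group)
        utils::write.csv(leak, file.path(out_dir, "leakage.csv"),
                         row.names = FALSE)
        grps <- split(leak$relative_index, leak$group)
        if (length(grps) >= 3L && !all(is.na(leak$relative_index))) {
          kw <- kruskal_wallis_dunn(grps)
          utils::write.csv(kw$pairwise, file.path(out_dir, "leakage_dunn.csv"),
                           row.names = FALSE)
          jsonlite::write_json(
            list(test = "Kruskal-Wallis", H = kw$omnibus$statistic,
                 p = kw$omnibus$p_value),
            file.path(out_dir, "leakage_omnibus.json"), auto_unbox = TRUE,
            digits = NA)
        }
      },
      compare = {
        df <- utils::read.csv(flags$`in`, stringsAsFactors = FALSE)
        grps <- split(df[[flags$value_col]], df[[flags$group_col]])
        if (length(grps) == 2L) {
          mw <- mann_whitney_u(grps[[1]], grps[[2]])
          jsonlite::write_json(
            list(test = mw$test, U = mw$statistic, p = mw$p_value,
                 method = mw$method, groups = names(grps)),
            file.path(out_dir, "comparison.json"), auto_unbox = TRUE,
            digits = NA)
        } else {
          kw <- kruskal_wallis_dunn(grps)
          utils::write.csv(kw$pairwise, file.path(out_dir, "dunn.csv"),
                           row.names = FALSE)
          jsonlite::write_json(
            list(test = "Kruskal-Wallis", H = kw$omnibus$statistic,
                 p = kw$omnibus$p_value),
            file.path(out_dir, "comparison.json"), auto_unbox = TRUE,
            digits = NA)
        }
      },
      pipeline = {
        cfg <- jsonlite::read_json(flags$config, simplifyVector = FALSE)
        cfg <- lapply(cfg, function(v)
          if (is.list(v) && !is.null(names(v)) &&
              all(vapply(v, function(e) length(e) == 1 && !is.list(e),
                         logical(1)))) unlist(v) else v)
        if (!is.null(cfg$band_nm)) cfg$band_nm <- as.numeric(unlist(cfg$band_nm))
        run_pipeline(run_config(cfg))
      },
      stop_tj("unknown subcommand '", cmd, "'\n", usage,
              class = "tjstorm_cli_error"))
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
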