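#' Pipeline run configuration
#'
#' Describes one analysis run over one or many cells: the input for each
#' cell (a [scene_spec()] to simulate, or a TIFF path to read), the channel
#' roles, per-channel segmentation parameters, and the morphometry/zoning
#' settings. Validation happens here, before any compute.
#'
#' @param cells named list; each element a [scene_spec()] or a TIFF path.
#' @param reference name of the single reference channel (e.g. `"LAMP1"`).
#' @param partners character vector of partner channels for object-based
#'   colocalization (may be empty).
#' @param ratio_pair `c(numerator, denominator)` channel names for
#'   ratiometric imaging, or `NULL`.
#' @param params a [segmentation_params()] used for every channel, or a
#'   named list of per-channel parameter sets (falling back to `.default`).
#' @param edges diameter bin edges.
#' @param zones a [zone_params()].
#' @param d_min_um diameter cutoff for large-object zone counts.
#' @param out_dir output directory for CSV tables and the manifest, or
#'   `NULL` to keep results in memory only.
#' @param seed integer seed governing simulation and any randomized step.
#' @return a `run_config` list.
#' @export
run_config <- function(cells, reference = "LAMP1", partners = character(),
                       ratio_pair = NULL, params = segmentation_params(),
                       edges = default_bin_edges(), zones = zone_params(),
                       d_min_um = 4, out_dir = NULL, seed = 1L) {
  if (length(reference) != 1L || !nzchar(reference)) {
    abort("exactly one reference channel is required")
  }
  if (!is.null(ratio_pair) && length(ratio_pair) != 2L) {
    abort("`ratio_pair` must be two channel names (numerator, denominator)")
  }
  if (length(cells) == 0L) abort("no cells to analyze")
  if (is.null(names(cells)) || any(!nzchar(names(cells)))) {
    names(cells) <- paste0("cell", seq_along(cells))
  }
  structure(list(cells = cells, reference = reference, partners = partners,
                 ratio_pair = ratio_pair, params = params, edges = edges,
                 zones = zones, d_min_um = d_min_um, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "run_config")
}

params_for <- function(config, channel) {
  p <- config$params
  if (inherits(p, "segmentation_params")) return(p)
  p[[channel]] %||% p[[".default"]] %||% segmentation_params()
}

analyze_one_cell <- function(config, cell_id, input) {
  stage <- "input"
  truth <- NULL
  tryCatch({
    if (inherits(input, "scene_spec")) {
      stage <- "simulate"
      scene <- render_scene(input)
      stack <- scene$stack
      truth <- scene$truth
    } else {
      stage <- "read"
      stack <- read_stack(input)
    }
    chans <- stack$channels
    needed <- unique(c(config$reference, config$partners, config$ratio_pair))
    missing <- setdiff(needed, chans)
    if (length(missing)) {
      abort(sprintf("channel(s) not in stack: %s", paste(missing, collapse = ", ")))
    }
    vs <- stack$voxel_size_um
    ref_params <- params_for(config, config$reference)

    stage <- "cell geometry"
    geom <- find_cell_geometry(get_channel(stack, config$reference), vs)

    stage <- "reference segmentation"
    seg <- segment_objects(stack, ref_params, channel = config$reference,
                           cell_geometry = geom)
    stage <- "spatial statistics"
    table <- seg$table |>
      add_surface_distance(seg$labels, vs) |>
      distal_distance(geom) |>
      add_zones(config$zones)

    stage <- "morphometry"
    distribution <- bin_by_diameter(table, config$edges)
    zc <- zone_counts(table, config$d_min_um, config$zones)
    vfrac <- if (nrow(table)) volume_fraction_above(table, 3) else NA_real_

    coloc <- list()
    for (p in config$partners) {
      stage <- paste("colocalization:", p)
      seg_p <- segment_partner(stack, params_for(config, p), channel = p,
                               cell_geometry = geom)
      cr <- centers_in_objects(seg_p$table, seg$labels, vs)
      coloc[[p]] <- list(partner_table = cr$partner,
                         reference_flags = cr$reference,
                         summary = double_positive_summary(cr, table))
    }

    ratio <- NULL
    if (!is.null(config$ratio_pair)) {
      stage <- "ratio imaging"
      a <- get_channel(stack, config$ratio_pair[1])
      b <- get_channel(stack, config$ratio_pair[2])
      d <- dim(a); s <- 16L
      blanks <- list(c(1L, s, 1L, s), c(1L, s, d[3] - s + 1L, d[3]),
                     c(d[2] - s + 1L, d[2], 1L, s),
                     c(d[2] - s + 1L, d[2], d[3] - s + 1L, d[3]))
      ri <- make_ratio_image(a, b, blanks)
      proj_a <- colMeans(a, dims = 1)
      bg_a <- estimate_background(proj_a, blanks)
      corr <- pmax(proj_a - bg_a, 0)
      th <- otsu_threshold(corr)
      lab2 <- label_components(array(corr > th, c(1L, dim(corr))), 26)[1, , ]
      ratio <- list(image = ri, objects = per_object_ratio(ri, lab2))
    }

    list(cell = cell_id, table = table, distribution = distribution,
         zone_counts = zc, volume_fraction_above_3um = vfrac,
         coloc = coloc, ratio = ratio, geometry = geom, truth = truth,
         labels = seg$labels, error = NULL)
  }, error = function(e) {
    list(cell = cell_id, error = sprintf("cell '%s', stage '%s': %s",
                                         cell_id, stage, conditionMessage(e)))
  })
}

write_cell_outputs <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  wr <- function(df, name) {
    path <- file.path(dir, name)
    df <- as.data.frame(df)
    df[] <- lapply(df, function(col) if (is.factor(col)) as.character(col) else col)
    utils::write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
  }
  wr(res$table, "objects.csv")
  wr(as.data.frame(res$distribution), "distribution.csv")
  wr(res$zone_counts, "zone_counts.csv")
  for (p in names(res$coloc)) {
    wr(res$coloc[[p]]$summary, paste0("coloc_", p, "_summary.csv"))
    wr(res$coloc[[p]]$partner_table, paste0("coloc_", p, "_objects.csv"))
  }
  if (!is.null(res$ratio)) wr(res$ratio$objects, "ratio_objects.csv")
  files
}

#' Run the full quantification pipeline
#'
#' For every cell: simulate or read the stack, locate the cell geometry,
#' segment the reference channel, compute distal distances and zones, bin
#' by size, count large objects per zone, run object-based colocalization
#' for each partner channel, and (when configured) build the ratio image.
#' A failing cell is reported with its id and stage; other cells continue.
#' With `out_dir` set, every per-cell table is written as CSV and a manifest
#' with MD5 checksums is produced; results are deterministic given the
#' configuration and seed.
#'
#' @param config a [run_config()].
#' @return a list of class `elysa_run` with `cells` (per-cell result lists),
#'   `errors`, `manifest` (tibble of written files and checksums, or `NULL`)
#'   and `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  results <- list()
  files <- character()
  for (cell_id in names(config$cells)) {
    res <- analyze_one_cell(config, cell_id, config$cells[[cell_id]])
    results[[cell_id]] <- res
    if (!is.null(res$error)) {
      warn(res$error)
      next
    }
    if (!is.null(config$out_dir)) {
      files <- c(files, write_cell_outputs(res, file.path(config$out_dir, cell_id)))
    }
  }
  manifest <- NULL
  if (!is.null(config$out_dir)) {
    log_path <- file.path(config$out_dir, "run_parameters.json")
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    ref_params <- params_for(config, config$reference)
    jsonlite::write_json(
      list(reference = config$reference, partners = config$partners,
           ratio_pair = config$ratio_pair, seed = config$seed,
           threshold = ref_params$threshold,
           connectivity = ref_params$connectivity,
           volume_filter_um3 = ref_params$volume_filter_um3,
           edges = config$edges,
           zones = unclass(config$zones), d_min_um = config$d_min_um,
           cells = names(config$cells)),
      log_path, auto_unbox = TRUE, digits = NA)
    files <- c(files, log_path)
    rel <- sub(paste0("^", normalizePath(config$out_dir), "/?"), "",
               normalizePath(files))
    manifest <- tibble::tibble(file = rel,
                               md5 = unname(tools::md5sum(files)))
    utils::write.csv(as.data.frame(manifest),
                     file.path(config$out_dir, "manifest.csv"),
                     row.names = FALSE)
  }
  errors <- purrr::compact(purrr::map(results, "error"))
  structure(list(cells = results, errors = errors, manifest = manifest,
                 config = config),
            class = "elysa_run")
}

#' @export
print.elysa_run <- function(x, ...) {
  ok <- sum(vapply(x$cells, function(r) is.null(r$error), logical(1)))
  cat(sprintf("<elysa_run> %d cell(s), %d succeeded, %d failed\n",
              length(x$cells), ok, length(x$errors)))
  for (e in x$errors) cat("  !", e, "\n")
  invisible(x)
}

# Compact letter display by insert-and-absorb: start with one set holding
# every group; for each significantly different pair split the sets that
# still join them; absorb subsets; letter the surviving sets.
cld_insert_absorb <- function(groups, sig_pairs) {
  sets <- list(groups)
  for (k in seq_len(nrow(sig_pairs))) {
    a <- sig_pairs$a[k]; b <- sig_pairs$b[k]
    new_sets <- list()
    for (s in sets) {
      if (a %in% s && b %in% s) {
        new_sets <- c(new_sets, list(setdiff(s, a)), list(setdiff(s, b)))
      } else new_sets <- c(new_sets, list(s))
    }
    keep <- rep(TRUE, length(new_sets))
    for (i in seq_along(new_sets)) {
      for (j in seq_along(new_sets)) {
        if (i != j && keep[j] &&
            all(new_sets[[i]] %in% new_sets[[j]]) &&
            (length(new_sets[[i]]) < length(new_sets[[j]]) || i > j)) {
          keep[i] <- FALSE; break
        }
      }
    }
    sets <- unique(new_sets[keep])
    sets <- sets[vapply(sets, length, integer(1)) > 0]
  }
  ord <- order(vapply(sets, function(s) min(match(s, groups)), numeric(1)))
  sets <- sets[ord]
  letters_for <- stats::setNames(rep("", length(groups)), groups)
  for (i in seq_along(sets)) {
    for (g in sets[[i]]) letters_for[g] <- paste0(letters_for[g], letters[i])
  }
  letters_for
}

#' Compare per-cell summaries across groups
#'
#' One-way ANOVA across groups followed by Tukey's honestly significant
#' difference test, with group means, SEMs, and a compact letter display:
#' groups sharing a letter are not significantly different at `alpha`.
#' The analysis unit is the per-cell summary value (one number per
#' oocyte/embryo), not the individual object.
#'
#' @param data a data frame of per-cell values.
#' @param value column of summary values (tidy-eval).
#' @param group column of group labels (tidy-eval).
#' @param alpha significance level (default 0.05).
#' @return an object of class `group_comparison` with elements `groups`
#'   (tibble: group, n, mean, sem, letter), `anova` (tibble: statistic, df,
#'   p_value), `tukey` (tibble of pairwise adjusted p-values), `note`.
#' @export
compare_groups <- function(data, value, group, alpha = 0.05) {
  df <- tibble::tibble(value = dplyr::pull(data, {{ value }}),
                       group = as.character(dplyr::pull(data, {{ group }})))
  df <- df[is.finite(df$value), , drop = FALSE]
  glev <- unique(df$group)
  if (length(glev) < 2L) abort("need at least two groups")
  if (any(table(df$group) < 2L)) abort("need at least two cells per group")
  df$group <- factor(df$group, levels = glev)
  summaries <- df |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$value),
                     sem = stats::sd(.data$value) / sqrt(dplyr::n()),
                     .groups = "drop")
  note <- NULL
  if (stats::sd(df$value) == 0) {
    note <- "all values identical: no differences to detect"
    groups <- dplyr::mutate(summaries, letter = "a",
                            group = as.character(.data$group))
    return(structure(list(groups = groups,
                          anova = tibble::tibble(statistic = NA_real_,
                                                 df = NA_real_,
                                                 p_value = NA_real_),
                          tukey = tibble::tibble(contrast = character(),
                                                 estimate = numeric(),
                                                 conf_low = numeric(),
                                                 conf_high = numeric(),
                                                 adj_p_value = numeric()),
                          note = note, alpha = alpha),
                     class = "group_comparison"))
  }
  fit <- stats::aov(value ~ group, data = df)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$group
  tukey <- tibble::tibble(contrast = rownames(tk), estimate = tk[, "diff"],
                          conf_low = tk[, "lwr"], conf_high = tk[, "upr"],
                          adj_p_value = tk[, "p adj"])
  sig <- tukey[!is.na(tukey$adj_p_value) & tukey$adj_p_value < alpha, ]
  pairs <- do.call(rbind, strsplit(sig$contrast, "-", fixed = TRUE))
  sig_pairs <- if (length(pairs)) tibble::tibble(a = pairs[, 1], b = pairs[, 2])
               else tibble::tibble(a = character(), b = character())
  lett <- cld_insert_absorb(levels(df$group), sig_pairs)
  groups <- dplyr::mutate(summaries, group = as.character(.data$group),
                          letter = unname(lett[.data$group]))
  structure(list(groups = groups,
                 anova = tibble::tibble(statistic = an[["F value"]][1],
                                        df = an[["Df"]][1],
                                        p_value = an[["Pr(>F)"]][1]),
                 tukey = tukey, note = note, alpha = alpha),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison> one-way ANOVA + Tukey HSD\n")
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  else cat(sprintf("  F = %.3f (df %d), p = %.4g\n",
                   x$anova$statistic, x$anova$df, x$anova$p_value))
  print(x$groups)
  invisible(x)
}

#' @export
tidy.group_comparison <- function(x, ...) x$tukey

#' @export
glance.group_comparison <- function(x, ...) x$anova
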