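#' Run the full enamel-complexity analysis pipeline
#'
#' Orchestrates images -> D -> species means -> tribe comparison ->
#' per-clade and unified PGLS -> single-trait phylogenetic signal ->
#' slope comparison, and returns all result tables. Two entry modes:
#' \describe{
#'   \item{image mode}{\code{images_dir} + \code{specimens}: D is
#'     estimated per trace, joined to the specimen table, and
#'     summarised to species means. Unreadable images fail soft (the
#'     specimen is skipped with a warning); structural problems (no
#'     usable specimens, tree overlap < 3) fail hard.}
#'   \item{summaries-only mode}{\code{summaries}: a species-summary
#'     table (as from [summarize_species()] or
#'     [equid_species_summary()]) is consumed directly; image stages
#'     and specimen-level distribution checks are skipped and the tribe
#'     comparison is reconstructed by exact pooling of the summaries.}
#' }
#' Regressions use species with both D and area; species lacking area
#' stay in the D-only tribe comparison. Taxa absent from the tree are
#' dropped from phylogenetic stages with a warning.
#'
#' @param config list with (any subset of) elements:
#'   \code{images_dir}, \code{specimens} (path or data.frame),
#'   \code{summaries} (path or data.frame), \code{tree} (newick path,
#'   string or \code{phylo}), \code{ranges} (path or data.frame; if
#'   given the tree is time-calibrated), \code{vartime} (default 1),
#'   \code{add_term} (default TRUE), \code{box_sizes}, \code{threshold},
#'   \code{clades} (default \code{c("Hipparionini", "Equini")}),
#'   \code{lambda_mode} (\code{"ML"} or a fixed numeric lambda),
#'   \code{alpha} (report significance level, default 0.05),
#'   \code{seed}, \code{out_dir} (write CSV/JSON tables if given).
#' @return object of class \code{enamel_report}: list of result tables
#'   (\code{per_specimen}, \code{species}, \code{tribe_comparison},
#'   \code{checks}, \code{regressions}, \code{signal},
#'   \code{slope_comparison}) plus a \code{provenance} block.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- utils::modifyList(list(
    vartime = 1, add_term = TRUE, box_sizes = default_box_sizes(),
    threshold = 0.5, clades = c("Hipparionini", "Equini"),
    lambda_mode = "ML", alpha = 0.05, seed = NULL, out_dir = NULL), config)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)

  per_specimen <- NULL; species <- NULL; checks <- NULL
  if (!is.null(cfg$summaries)) {
    species <- if (is.data.frame(cfg$summaries)) cfg$summaries
               else utils::read.csv(cfg$summaries, stringsAsFactors = FALSE)
  } else {
    if (is.null(cfg$images_dir) || is.null(cfg$specimens))
      stop("need either 'summaries' or both 'images_dir' and 'specimens'")
    d_tab <- estimate_D_dir(cfg$images_dir, threshold = cfg$threshold,
                            sizes = cfg$box_sizes)
    spec <- load_specimens(cfg$specimens)
    per_specimen <- merge(spec, d_tab, by = "specimen_id")
    if (nrow(per_specimen) == 0L) stop("no usable specimens")
    species <- summarize_species(per_specimen)
    by_tribe <- split(per_specimen$D, per_specimen$tribe)
    if (all(vapply(by_tribe, length, 1L) >= 3L))
      checks <- distribution_checks(by_tribe)
  }
  species$taxon <- normalize_taxon(species$taxon)

  tribes <- intersect(cfg$clades, unique(species$tribe))
  tribe_comparison <- NULL
  if (length(tribes) == 2L) {
    ga <- pooled_from_species(species, tribes[1])
    gb <- pooled_from_species(species, tribes[2])
    wt <- welch_t(ga, gb)
    tribe_comparison <- data.frame(
      t = wt$t, df = wt$df, p = wt$p,
      mean_1 = ga$mean, mean_2 = gb$mean,
      group_1 = tribes[1], group_2 = tribes[2],
      significant = wt$p < cfg$alpha)
  }

  regressions <- NULL; signal <- NULL; slope_comparison <- NULL
  if (!is.null(cfg$tree)) {
    tree <- cfg$tree
    if (!inherits(tree, "phylo")) {
      txt <- if (file.exists(tree)) paste(readLines(tree), collapse = "")
             else tree
      tree <- parse_newick(txt)
    }
    if (!is.null(cfg$ranges))
      tree <- time_calibrate(tree, read_ranges(cfg$ranges),
                             vartime = cfg$vartime,
                             add_term = cfg$add_term)
    if (is.null(tree$edge.length))
      stop("tree has no branch lengths and no ranges table was supplied")
    fit_groups <- c(as.list(tribes),
                    if (length(tribes) == 2L) list(tribes))
    fits <- list(); sig_rows <- list()
    for (g in fit_groups) {
      label <- if (length(g) == 2L) "unified" else g
      sub <- species[species$tribe %in% g & species$n_area > 0 &
                     !is.na(species$mean_D), , drop = FALSE]
      dat <- data.frame(taxon = sub$taxon, x = sub$mean_area,
                        y = sub$mean_D, stringsAsFactors = FALSE)
      on_tree <- dat$taxon %in% tree$tip.label
      if (any(!on_tree))
        warning(sum(!on_tree), " taxa in '", label,
                "' absent from tree; dropped")
      dat <- dat[on_tree, , drop = FALSE]
      if (nrow(dat) < 3L) {
        warning("clade '", label, "': fewer than 3 taxa on tree; skipped")
        next
      }
      sub_tree <- ape::keep.tip(tree, dat$taxon)
      V <- phylo_covariance(sub_tree)
      fit <- if (identical(cfg$lambda_mode, "ML")) profile_lambda(dat, V)
             else gls_fit(dat, V, lambda = as.numeric(cfg$lambda_mode))
      fits[[label]] <- fit
      for (tr in c("D", "area")) {
        vals <- if (tr == "D") species$mean_D else species$mean_area
        v <- stats::setNames(vals, species$taxon)
        v <- v[species$tribe %in% g]
        v <- v[!is.na(v) & names(v) %in% sub_tree$tip.label]
        sig <- if (length(v) >= 3L && stats::var(v) > 0)
          lambda_signal(v, sub_tree)
        else list(lambda = NA_real_, ci = c(NA_real_, NA_real_),
                  n = length(v))
        sig_rows[[paste(label, tr)]] <- data.frame(
          clade = label, trait = tr, lambda = sig$lambda,
          ci_lower = sig$ci[1], ci_upper = sig$ci[2], n = sig$n)
      }
    }
    if (length(fits)) {
      regressions <- do.call(rbind, lapply(names(fits), function(nm) {
        f <- fits[[nm]]
        data.frame(clade = nm, lambda = f$lambda,
                   ci_lower = f$lambda_ci[1], ci_upper = f$lambda_ci[2],
                   slope = f$slope, se = f$se_slope, t = f$t_slope,
                   p = f$p_slope, r2_multiple = f$r2_multiple,
                   r2_adjusted = f$r2_adjusted, n = f$n)
      }))
      signal <- do.call(rbind, sig_rows)
      rownames(signal) <- NULL
    }
    if (length(tribes) == 2L && all(tribes %in% names(fits))) {
      cs <- compare_slopes(fits[[tribes[1]]], fits[[tribes[2]]])
      slope_comparison <- data.frame(
        t = cs$t, df = cs$df, p = cs$p,
        significant = cs$p < cfg$alpha)
    }
  }

  report <- structure(list(
    per_specimen = per_specimen, species = species,
    tribe_comparison = tribe_comparison, checks = checks,
    regressions = regressions, signal = signal,
    slope_comparison = slope_comparison,
    provenance = list(seed = cfg$seed, alpha = cfg$alpha,
                      box_sizes = cfg$box_sizes, vartime = cfg$vartime,
                      add_term = cfg$add_term,
                      lambda_mode = cfg$lambda_mode,
                      package_version = as.character(
                        utils::packageVersion("enamelD")),
                      config = cfg[setdiff(names(cfg), "out_dir")])),
    class = "enamel_report")
  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir)
  report
}

#' @export
print.enamel_report <- function(x, ...) {
  cat("enamel-complexity analysis report\n")
  for (nm in c("tribe_comparison", "regressions", "signal",
               "slope_comparison")) {
    if (!is.null(x[[nm]])) {
      cat("\n--", nm, "--\n")
      print(x[[nm]], digits = 4)
    }
  }
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' One CSV per result table plus a JSON provenance block, into
#' \code{dir} (created if needed).
#'
#' @param report an \code{enamel_report} from [run_pipeline()].
#' @param dir output directory.
#' @return \code{dir}, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("per_specimen", "species", "tribe_comparison", "regressions",
               "signal", "slope_comparison")) {
    if (!is.null(report[[nm]]))
      utils::write.csv(report[[nm]], file.path(dir, paste0(nm, ".csv")),
                       row.names = FALSE)
  }
  jsonlite::write_json(report$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  invisible(dir)
}

#' Command-line entry point
#'
#' Subcommand dispatcher used by the installed \code{enameld} script.
#' Subcommands: \code{trace-d} (estimate D for a directory of images),
#' \code{summarize} (specimen CSV with D column -> species summary),
#' \code{compare} (species summary -> tribe Welch t-test),
#' \code{pgls} (species summary + tree [+ ranges] -> regression tables),
#' \code{simulate} (write a synthetic curve image), and \code{report}
#' (full pipeline from a summaries CSV + tree). Flags are
#' \code{--key value} pairs.
#'
#' @param argv character vector of command-line arguments.
#' @return integer exit code: 0 success, 1 runtime failure, 2 usage
#'   error.
#' @export
cli_main <- function(argv) {
  usage <- paste(
    "usage: enameld <subcommand> [--key value ...]",
    "  trace-d   --images DIR --out CSV [--threshold T]",
    "  summarize --specimens CSV --out CSV",
    "  compare   --summaries CSV [--out CSV]",
    "  pgls      --summaries CSV --tree NWK [--ranges CSV] [--lambda ML|x]",
    "            [--out DIR]",
    "  simulate  --kind K [--iterations N] [--px W] --out PNG",
    "  report    --summaries CSV [--tree NWK] [--ranges CSV] --out DIR",
    sep = "\n")
  if (length(argv) < 1L) { message(usage); return(2L) }
  cmd <- argv[1]
  opts <- tryCatch(parse_argv(argv[-1]), error = function(e) {
    message("argument error: ", conditionMessage(e), "\n", usage)
    NULL
  })
  if (is.null(opts)) return(2L)
  run <- function(expr) tryCatch({ expr; 0L }, error = function(e) {
    message("error: ", conditionMessage(e)); 1L
  })
  need <- function(...) {
    miss <- setdiff(c(...), names(opts))
    if (length(miss)) stop("missing required flag(s): --",
                           paste(miss, collapse = " --"), call. = FALSE)
  }
  switch(cmd,
    "trace-d" = run({
      need("images", "out")
      thr <- if ("threshold" %in% names(opts))
        as.numeric(opts$threshold) else 0.5
      utils::write.csv(estimate_D_dir(opts$images, threshold = thr),
                       opts$out, row.names = FALSE)
    }),
    summarize = run({
      need("specimens", "out")
      df <- utils::read.csv(opts$specimens, stringsAsFactors = FALSE)
      utils::write.csv(summarize_species(df), opts$out, row.names = FALSE)
    }),
    compare = run({
      need("summaries")
      rep <- run_pipeline(list(summaries = opts$summaries))
      print(rep$tribe_comparison)
      if ("out" %in% names(opts))
        utils::write.csv(rep$tribe_comparison, opts$out, row.names = FALSE)
    }),
    pgls = run({
      need("summaries", "tree")
      lm_ <- if ("lambda" %in% names(opts) && opts$lambda != "ML")
        as.numeric(opts$lambda) else "ML"
      rep <- run_pipeline(list(summaries = opts$summaries, tree = opts$tree,
                               ranges = opts$ranges, lambda_mode = lm_,
                               out_dir = opts$out))
      print(rep$regressions)
    }),
    simulate = run({
      need("kind", "out")
      it <- if ("iterations" %in% names(opts))
        as.integer(opts$iterations) else 5L
      px <- if ("px" %in% names(opts)) as.integer(opts$px) else 729L
      write_trace(generate_curve(opts$kind, iterations = it,
                                 raster_px = px)$trace, opts$out)
    }),
    report = run({
      need("summaries", "out")
      run_pipeline(list(summaries = opts$summaries, tree = opts$tree,
                        ranges = opts$ranges, out_dir = opts$out))
    }),
    { message("unknown subcommand '", cmd, "'\n", usage); 2L })
}

parse_argv <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    if (!startsWith(args[i], "--")) stop("expected --flag, got '", args[i], "'")
    key <- substring(args[i], 3)
    if (i + 1L > length(args)) stop("flag --", key, " needs a value")
    opts[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  opts
}
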