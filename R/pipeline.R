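.default_run_config <- function() {
  list(
    simulation = list(),     # overrides passed to simulation_config()
    input = NULL,            # or list(fasta=, meta=, aln_dir=) for real data
    window = list(window = 200L, shift = 10L, k = 5L, ma_span = 1L),
    model = "k80",
    intact_set = c("uvrA", "uvrDp", "mfd", "groEL", "groES", "galU"),
    degraded_set = c("uvrB", "uvrC", "mutY"),
    ratio_intact_set = NULL, # default: every gene not in degraded_set
    alpha = 0.05,
    seed = 1L,
    out_dir = NULL
  )
}

#' Validate and normalize a run configuration
#'
#' Accepts a YAML file path or a list; fills defaults (W = 200, s = 10,
#' k = 5, model = k80, alpha = 0.05) and rejects unknown keys. Exactly one of
#' \code{simulation} (overrides for \code{\link{simulation_config}}) or
#' \code{input} (\code{fasta}, \code{meta}, \code{aln_dir} paths) drives the
#' run; the default is a simulated dataset.
#'
#' @param x Path to a YAML config or a list of settings.
#' @return Normalized \code{run_config} list.
#' @export
validate_config <- function(x = list()) {
  if (is.character(x)) x <- yaml::read_yaml(x)
  if (!is.list(x)) stop("config must be a list or a YAML file path")
  defaults <- .default_run_config()
  unknown <- setdiff(names(x), names(defaults))
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- defaults
  for (k in names(x)) {
    if (k == "window" && is.list(x[[k]])) {
      wun <- setdiff(names(x[[k]]), names(defaults$window))
      if (length(wun)) stop("unknown window key(s): ", paste(wun, collapse = ", "))
      cfg$window[names(x[[k]])] <- x[[k]]
    } else cfg[[k]] <- x[[k]]
  }
  # window_spec enforces k <= W, odd ma_span, positive shift
  do.call(window_spec, cfg$window)
  if (!is.numeric(cfg$alpha) || cfg$alpha <= 0 || cfg$alpha >= 1) {
    stop("alpha must be in (0,1)")
  }
  cfg$model <- match.arg(cfg$model, c("k80", "p", "jc69", "hky"))
  if (length(intersect(cfg$degraded_set, cfg$intact_set))) {
    stop("degraded_set and intact_set overlap: ",
         paste(intersect(cfg$degraded_set, cfg$intact_set), collapse = ", "))
  }
  if (!is.null(cfg$input)) {
    need <- c("fasta", "meta", "aln_dir")
    miss <- setdiff(need, names(cfg$input))
    if (length(miss)) stop("input config missing: ", paste(miss, collapse = ", "))
    for (p in unlist(cfg$input[need])) {
      if (!file.exists(p)) stop("input path does not exist: ", p)
    }
  }
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

.config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(cfg[setdiff(names(cfg), "out_dir")], f)
  unname(tools::md5sum(f))
}

#' Run the full comparative pipeline
#'
#' Simulates (or loads) a gene-by-symbiont panel, computes the three
#' parameter tables (outgroup distance, GC percent, repeat density) plus the
#' dN/dS table, the three round-robin paired-t pair matrices (all-genes lower
#' half, intact-genes upper half), the degraded/intact clade-ratio analyses,
#' and the three cross-parameter regressions. With \code{out_dir} set, all
#' tables are written as TSV/JSON stamped with the seed and a config hash;
#' any stage failure aborts with the stage name and removes partial outputs.
#'
#' @param config A \code{run_config} from \code{\link{validate_config}} (or
#'   anything it accepts).
#' @return A \code{rge_run} list: \code{tables} (distance, gc,
#'   repeat_density, dnds), \code{pair_matrices}, \code{ratios},
#'   \code{regressions}, \code{clade_summaries}, \code{summary}, and (for
#'   simulated runs) \code{sim} with the ground truth.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- if (inherits(config, "run_config")) config else validate_config(config)
  stage <- "setup"
  wrote <- character(0)
  out_dir <- cfg$out_dir
  result <- tryCatch({
    stage <- "data"
    sim <- NULL
    if (is.null(cfg$input)) {
      sim_args <- cfg$simulation
      if (is.null(sim_args$seed)) sim_args$seed <- cfg$seed
      sim <- simulate_dataset(do.call(simulation_config, sim_args))
      gm <- sim$matrix
      alignments <- sim$alignments
    } else {
      gm <- build_matrix(read_fasta(cfg$input$fasta),
                         read_metadata(cfg$input$meta))
      alignments <- read_alignment_dir(cfg$input$aln_dir)
    }
    spec <- do.call(window_spec, cfg$window)

    stage <- "parameter tables"
    tabs <- list(
      distance = distance_table(gm, alignments, cfg$model),
      gc = gc_table(gm),
      repeat_density = suppressWarnings(repeat_table(gm, spec)),
      dnds = dnds_table(gm, alignments)
    )
    dnds_clades <- clade_dnds(gm, alignments)

    genes <- gm$gene_order
    intact <- intersect(cfg$intact_set, genes)
    ratio_intact <- if (is.null(cfg$ratio_intact_set)) {
      setdiff(genes, cfg$degraded_set)
    } else intersect(cfg$ratio_intact_set, genes)
    degraded <- intersect(cfg$degraded_set, genes)

    stage <- "pair matrices"
    pms <- lapply(tabs[c("distance", "gc", "repeat_density")], function(tb) {
      pair_matrix(tb, lower_genes = genes, upper_genes = intact)
    })

    stage <- "ratio analysis"
    ratios <- if (length(degraded) && length(ratio_intact)) {
      lapply(tabs[c("distance", "gc", "repeat_density")], function(tb) {
        ratio_analysis(tb, degraded, ratio_intact)
      })
    } else list()

    stage <- "regressions"
    regs <- list(
      distance_gc = parameter_regression(tabs$distance, tabs$gc),
      distance_repeat = parameter_regression(tabs$distance, tabs$repeat_density),
      gc_repeat = parameter_regression(tabs$gc, tabs$repeat_density)
    )

    stage <- "summaries"
    # degraded genes legitimately have no dN/dS in their degraded clade
    sums <- lapply(tabs, function(tb) suppressWarnings(clade_summary(tb)))
    summary <- list(
      seed = cfg$seed,
      config_hash = .config_hash(cfg),
      alpha = cfg$alpha,
      clade_means = lapply(sums, function(s) {
        stats::aggregate(mean ~ clade, data = s, FUN = mean)
      }),
      ratio_means = lapply(ratios, function(r) {
        r[c("degraded_mean", "degraded_sd", "intact_mean", "intact_sd", "p")]
      }),
      regressions = regs
    )

    structure(list(config = cfg, tables = tabs, dnds_clades = dnds_clades,
                   pair_matrices = pms, ratios = ratios, regressions = regs,
                   clade_summaries = sums, summary = summary, sim = sim),
              class = "rge_run")
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })

  if (!is.null(out_dir)) {
    ok <- FALSE
    on.exit(if (!ok) unlink(wrote), add = TRUE)
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    stamp <- sprintf("# seed=%d config=%s", cfg$seed, result$summary$config_hash)
    wfile <- function(name) { p <- file.path(out_dir, name); wrote <<- c(wrote, p); p }
    for (nm in names(result$tables)) {
      p <- wfile(paste0(nm, ".tsv"))
      writeLines(stamp, p)
      tmp <- tempfile(); write_parameter_table(result$tables[[nm]], tmp)
      file.append(p, tmp); unlink(tmp)
    }
    p <- wfile("dnds_clades.tsv")
    writeLines(stamp, p)
    tmp <- tempfile()
    write.table(result$dnds_clades, tmp, sep = "\t", quote = FALSE,
                row.names = FALSE)
    file.append(p, tmp); unlink(tmp)
    for (nm in names(result$pair_matrices)) {
      pm <- result$pair_matrices[[nm]]
      p <- wfile(paste0("pairs_", nm, ".tsv"))
      writeLines(stamp, p)
      tmp <- tempfile(); write_parameter_table(pm$combined, tmp)
      file.append(p, tmp); unlink(tmp)
    }
    if (length(result$ratios)) {
      p <- wfile("ratios.tsv")
      rt <- do.call(rbind, lapply(names(result$ratios), function(nm) {
        r <- result$ratios[[nm]]
        data.frame(parameter = nm, gene = names(r$ratios),
                   ratio = unname(r$ratios),
                   group = ifelse(names(r$ratios) %in% cfg$degraded_set,
                                  "degraded", "intact"))
      }))
      writeLines(stamp, p)
      tmp <- tempfile()
      write.table(rt, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
      file.append(p, tmp); unlink(tmp)
    }
    p <- wfile("summary.json")
    jsonlite::write_json(result$summary, p, auto_unbox = TRUE, digits = NA,
                         force = TRUE)
    ok <- TRUE
  }
  result
}

#' @export
print.rge_run <- function(x, ...) {
  cat("rge_run (seed", x$config$seed, ")\n")
  for (nm in c("distance", "gc", "repeat_density")) {
    s <- x$clade_summaries[[nm]]
    agg <- stats::aggregate(mean ~ clade, data = s, FUN = mean)
    cat(sprintf("  %-14s clade means: %s\n", nm,
                paste(sprintf("%s=%.3f", agg$clade, agg$mean), collapse = ", ")))
  }
  dd <- x$dnds_clades[!is.na(x$dnds_clades$mean), ]
  if (nrow(dd)) {
    agg <- stats::aggregate(mean ~ clade, data = dd, FUN = mean)
    cat(sprintf("  %-14s clade means: %s (within-clade pairs)\n", "dN/dS",
                paste(sprintf("%s=%.3f", agg$clade, agg$mean), collapse = ", ")))
  }
  if (length(x$ratios)) {
    for (nm in names(x$ratios)) {
      r <- x$ratios[[nm]]
      cat(sprintf("  ratio I/II %-11s degraded %.3f+/-%.3f intact %.3f+/-%.3f (MWU p=%.3g)\n",
                  nm, r$degraded_mean, r$degraded_sd, r$intact_mean, r$intact_sd, r$p))
    }
  }
  rg <- x$regressions$gc_repeat
  cat(sprintf("  repeat ~ GC regression: slope %.3f, R %.3f, p %.3g (n=%d)\n",
              rg$slope, rg$r, rg$p, rg$n))
  invisible(x)
}
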