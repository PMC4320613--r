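# End-to-end orchestration: run all stages in dependency order into an
# output directory, with a reproducible run manifest, and render summary
# figures/text from the stage outputs.

#' Run the full acceptor-scan pipeline
#'
#' Stages, in order: (1) obtain genome + annotation (either from
#' `config$genome`/`config$annotation` paths or by generating a synthetic
#' genome from `config$synthetic`), (2) derive introns and extract acceptor
#' windows (`sites.tsv`), (3) scan for purine-rich sites and G tracts
#' (`calls.tsv`), (4) train a strength model on the non-purine-rich
#' acceptors versus random decoys and score every site (`scores.tsv`),
#' (5) classify alternative-splicing events and associate them with sites
#' (`events.tsv`), (6) positional profiles of the purine-rich versus
#' constitutive site sets (`profile.tsv`), (7) emergence summary of an
#' ortholog table (`emergence.tsv`; the packaged vertebrate panel by
#' default), and a `manifest.json` with input hashes and per-stage record
#' counts. A failing stage leaves the completed outputs in place and an
#' error manifest.
#'
#' @param config A named list (or path to a JSON file): either
#'   `synthetic` (arguments for [repa_sim_config()]) or both `genome` and
#'   `annotation` (file paths); optional `params` (`threshold`,
#'   `intron_span`, `exon_span`, `gmin`, `gmax`), `ortholog_table` (TSV
#'   path; `"packaged"` or absent for the built-in panel, `"none"` to
#'   skip), `reference_proportions` (named list), `seed`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the stage outputs and the manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  config <- validate_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- config$params
  manifest <- list(tool = "repascan",
                   version = as.character(utils::packageVersion("repascan")),
                   seed = config$seed, params = p, stages = list())
  set.seed(config$seed)
  outputs <- list()
  stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e) {
      manifest$stages[[name]] <<- list(status = "error",
                                       message = conditionMessage(e))
      manifest$status <<- paste0("failed at stage ", name)
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
      stop("stage ", name, " failed: ", conditionMessage(e),
           call. = FALSE)
    })
    res
  }

  # stage 1: inputs
  if (!is.null(config$synthetic)) {
    sim <- stage("input", function() {
      do.call(repa_sim_config, config$synthetic)
    })
    sim <- stage("input", function() generate_genome(sim))
    genome <- sim$genome; models <- sim$annotation
    manifest$stages$input <- list(status = "ok", source = "synthetic",
                                  n_genes = sim$counts$n_genes,
                                  n_transcripts = sim$counts$n_transcripts)
    outputs$truth <- sim$truth
  } else {
    genome <- config$genome; gtf <- config$annotation
    models <- stage("input", function() parse_annotation(gtf))
    manifest$input_hashes <- list(
      genome = unname(tools::md5sum(genome)),
      annotation = unname(tools::md5sum(gtf)))
    manifest$stages$input <- list(
      status = "ok", source = "files",
      n_transcripts = length(unique(models$transcript_id)))
  }

  # stage 2: sites
  sites <- stage("sites", function() {
    introns <- derive_introns(models)
    extract_windows(genome, introns, p$intron_span, p$exon_span)
  })
  write_sites_tsv(sites, file.path(out_dir, "sites.tsv"))
  write_sites_bed(sites, file.path(out_dir, "sites.bed"))
  manifest$stages$sites <- list(status = "ok", n_sites = nrow(sites))
  outputs$sites <- sites

  # stage 3: scan
  calls <- stage("scan", function() {
    scan_sites(sites, threshold = p$threshold, min_len = p$gmin,
               max_len = p$gmax)
  })
  utils::write.table(calls, file.path(out_dir, "calls.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest$stages$scan <- list(
    status = "ok", n_sites = nrow(calls),
    n_repa = sum(calls$is_repa),
    n_repa_with_tract = sum(calls$is_repa & calls$n_tracts > 0))
  outputs$calls <- calls

  # stage 4: strength scores
  scores <- stage("strength", function() {
    L <- p$intron_span + p$exon_span
    full <- !sites$truncated & nchar(sites$window) == L &
      grepl("^[ACGT]+$", sites$window)
    sig <- sites$window[full & !calls$is_repa[match(sites$site_id,
                                                    calls$site_id)]]
    decoys <- vapply(seq_along(sig), function(i) {
      paste(sample(DNA_BASES, L, replace = TRUE), collapse = "")
    }, "")
    model <- train_strength_model(sig, decoys)
    data.frame(site_id = sites$site_id[full],
               score = score_site(model, sites$window[full]),
               stringsAsFactors = FALSE)
  })
  utils::write.table(scores, file.path(out_dir, "scores.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest$stages$strength <- list(status = "ok", n_scored = nrow(scores))
  outputs$scores <- scores

  # stage 5: AS events
  events <- stage("events", function() detect_as_events(models))
  assoc <- stage("events", function() associate_sites(events, sites))
  utils::write.table(events, file.path(out_dir, "events.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(assoc, file.path(out_dir, "site_as_status.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest$stages$events <- list(status = "ok", n_events = nrow(events),
                                 n_alternative = sum(assoc$is_alternative))
  outputs$events <- events; outputs$site_as_status <- assoc

  # stage 6: profiles
  prof <- stage("profile", function() {
    is_repa <- calls$is_repa[match(sites$site_id, calls$site_id)]
    keep <- !sites$truncated
    list(repa = if (any(keep & is_repa)) {
      position_profile(sites[keep & is_repa, , drop = FALSE])
    },
    constitutive = if (any(keep & !is_repa)) {
      position_profile(sites[keep & !is_repa, , drop = FALSE])
    })
  })
  prof_df <- do.call(rbind, lapply(names(prof), function(g) {
    pr <- prof[[g]]
    if (is.null(pr)) return(NULL)
    data.frame(group = g, position = pr$positions,
               t(pr$freq), purine_freq = pr$purine_freq,
               n_sites = pr$n_sites, stringsAsFactors = FALSE)
  }))
  utils::write.table(prof_df, file.path(out_dir, "profile.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest$stages$profile <- list(
    status = "ok",
    groups = names(prof)[!vapply(prof, is.null, TRUE)])
  outputs$profiles <- prof

  # stage 7: emergence
  if (!identical(config$ortholog_table, "none")) {
    emer <- stage("emergence", function() {
      tab <- if (is.null(config$ortholog_table) ||
                 identical(config$ortholog_table, "packaged")) {
        repa_vertebrate_table()
      } else {
        load_ortholog_table(config$ortholog_table)
      }
      call_emergence(presence_matrix(tab, gmin = p$gmin))
    })
    utils::write.table(emer, file.path(out_dir, "emergence.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    es <- summarize_emergence(emer)
    manifest$stages$emergence <- list(
      status = "ok", n_genes = es$n_rows, n_complete = es$n_complete,
      n_mammalian = es$n_mammalian,
      pct_mammalian = es$pct_mammalian)
    outputs$emergence <- emer
    outputs$emergence_summary <- es
  }

  manifest$status <- "ok"
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  outputs$manifest <- manifest
  invisible(outputs)
}

validate_pipeline_config <- function(config) {
  if (!is.list(config)) stop("config error: config must be a list")
  if (is.null(config$synthetic)) {
    for (f in c("genome", "annotation")) {
      if (is.null(config[[f]])) {
        stop("config error: missing field '", f,
             "' (or provide 'synthetic')")
      }
    }
    for (f in c("genome", "annotation")) {
      if (!file.exists(config[[f]])) {
        stop("config error: file for '", f, "' not found: ", config[[f]])
      }
    }
  }
  defaults <- list(threshold = 0.60, intron_span = 20L, exon_span = 3L,
                   gmin = 3L, gmax = 8L)
  p <- config$params %||% list()
  unknown <- setdiff(names(p), names(defaults))
  if (length(unknown)) {
    stop("config error: unknown param field(s): ",
         paste(unknown, collapse = ", "))
  }
  config$params <- utils::modifyList(defaults, p)
  if (config$params$threshold < 0 || config$params$threshold >= 1) {
    stop("config error: field 'params$threshold' must be in [0, 1)")
  }
  config$seed <- as.integer(config$seed %||% 1L)
  config
}

#' Render summary figures and a text report from pipeline outputs
#'
#' Writes vector (SVG) figures -- positional A/G profile, first-G position
#' histogram, run-length distribution, alternative-splicing type
#' distribution, emergence summary -- plus `summary.txt` with the site
#' funnel (sites, purine-rich, with G tract, alternative). Rendering is
#' deterministic given the outputs; empty inputs yield placeholder panels
#' with a warning rather than an error.
#'
#' @param out_dir Directory produced by [run_pipeline()].
#' @param reference_proportions Optional named vector for the event-type
#'   fold-enrichment panel.
#' @return Invisibly, the paths written.
#' @export
render_report <- function(out_dir, reference_proportions = NULL) {
  paths <- character(0)
  dev_open <- function(name) {
    f <- file.path(out_dir, paste0(name, ".svg"))
    grDevices::svg(f, width = 6, height = 4)
    paths <<- c(paths, f)
    f
  }
  placeholder <- function(msg) {
    warning(msg)
    graphics::plot.new()
    graphics::text(0.5, 0.5, paste0("(", msg, ")"))
  }

  prof_path <- file.path(out_dir, "profile.tsv")
  calls_path <- file.path(out_dir, "calls.tsv")
  calls <- if (file.exists(calls_path)) {
    utils::read.table(calls_path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  }

  dev_open("profile")
  if (file.exists(prof_path)) {
    pr <- utils::read.table(prof_path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    groups <- unique(pr$group)
    cols <- stats::setNames(c("black", "magenta")[seq_along(groups)],
                            groups)
    first <- TRUE
    for (g in groups) {
      sub <- pr[pr$group == g, ]
      ord <- order(sub$position)
      if (first) {
        graphics::plot(seq_along(sub$position),
                       100 * sub$purine_freq[ord], type = "b",
                       col = cols[[g]], ylim = c(0, 100), xaxt = "n",
                       xlab = "position", ylab = "% A/G",
                       main = "A/G content at the 3' splice site")
        graphics::axis(1, at = seq_along(sub$position),
                       labels = sub$position[ord])
        first <- FALSE
      } else {
        graphics::lines(seq_along(sub$position),
                        100 * sub$purine_freq[ord], type = "b",
                        col = cols[[g]])
      }
    }
    graphics::legend("topleft", legend = groups, col = cols, lty = 1,
                     bty = "n")
  } else placeholder("no profile data")
  grDevices::dev.off()

  dev_open("first_g")
  if (!is.null(calls) && any(!is.na(calls$first_g) & calls$is_repa)) {
    h <- first_g_histogram(calls[calls$is_repa, , drop = FALSE])
    graphics::barplot(h, xlab = "first G position", ylab = "3'SS count",
                      main = "First G of the representative tract")
  } else placeholder("no G tracts to plot")
  grDevices::dev.off()

  dev_open("run_length")
  if (!is.null(calls) && any(!is.na(calls$tract_length) & calls$is_repa)) {
    d <- run_length_distribution(calls[calls$is_repa, , drop = FALSE])
    d <- d[d > 0]
    graphics::pie(d, labels = paste0("G", names(d), " (", d, ")"),
                  main = "G-tract run lengths")
  } else placeholder("no G tracts to plot")
  grDevices::dev.off()

  as_path <- file.path(out_dir, "site_as_status.tsv")
  dev_open("as_types")
  if (file.exists(as_path)) {
    st <- utils::read.table(as_path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, na.strings = NULL)
    st$event_types[is.na(st$event_types)] <- ""
    if (any(nzchar(st$event_types))) {
      td <- type_distribution(st, reference_proportions)
      graphics::barplot(stats::setNames(td$proportion, td$event_type),
                        las = 2, ylab = "proportion",
                        main = "Alternative-splicing event types")
    } else placeholder("no alternative sites")
  } else placeholder("no AS status data")
  grDevices::dev.off()

  emer_path <- file.path(out_dir, "emergence.tsv")
  summary_lines <- character(0)
  dev_open("emergence")
  if (file.exists(emer_path)) {
    em <- utils::read.table(emer_path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    es <- summarize_emergence(em)
    graphics::barplot(c(mammalian = es$n_mammalian,
                        pre_mammalian = es$n_pre_mammalian,
                        absent = es$n_absent),
                      ylab = "complete genes",
                      main = "Clade of emergence")
    summary_lines <- c(summary_lines,
                       sprintf("emergence: n_complete=%d pct_mammalian=%.1f",
                               es$n_complete, es$pct_mammalian))
  } else placeholder("no emergence data")
  grDevices::dev.off()

  if (!is.null(calls)) {
    summary_lines <- c(
      sprintf("sites scanned: %d", nrow(calls)),
      sprintf("purine-rich (REPA) acceptors: %d", sum(calls$is_repa)),
      sprintf("with >=1 G tract: %d",
              sum(calls$is_repa & calls$n_tracts > 0)),
      if (file.exists(as_path)) {
        st <- utils::read.table(as_path, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
        repa_ids <- calls$site_id[calls$is_repa & calls$n_tracts > 0]
        alt <- st$is_alternative[st$site_id %in% repa_ids]
        sprintf("G-tract sites associated with AS: %d of %d (%.0f%%)",
                sum(alt), length(alt),
                if (length(alt)) 100 * mean(alt) else 0)
      },
      summary_lines)
  }
  sf <- file.path(out_dir, "summary.txt")
  writeLines(summary_lines, sf)
  invisible(c(paths, sf))
}
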