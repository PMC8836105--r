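## End-to-end orchestration of the two analysis arms with deterministic,
## diff-able TSV reports. Every number written here is recomputed by the
## module functions; the pipeline adds no logic of its own.

.provenance_header <- function(config, seed = NA) {
  tf <- tempfile()
  on.exit(unlink(tf))
  jsonlite::write_json(config, tf, auto_unbox = TRUE, digits = NA,
                       force = TRUE, null = "null")
  hash <- unname(tools::md5sum(tf))
  c(sprintf("# ppzcompare %s", as.character(utils::packageVersion("ppzcompare"))),
    sprintf("# config_md5 %s", hash),
    sprintf("# seed %s", as.character(seed)))
}

.write_report <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.load_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    jsonlite::read_json(config, simplifyVector = TRUE)
  } else {
    config
  }
}

#' Run the conservation arm end to end
#'
#' Reads an aligned FASTA plus labels sidecar (or takes an
#' `aligned_group_set` directly), then writes: conserved-position counts per
#' group with and without the configured excluded clades, the column
#' classification table (with reference full-length positions when reference
#' ids are configured), the charge-swap table, optional motif reports and
#' logo matrices, per-group identity matrices, and a neighbor-joining newick
#' over all sequences. Reruns on identical inputs are byte-identical.
#'
#' @param config List (or path to a JSON file) with entries: `alignment`
#'   (FASTA path) and `labels` (TSV path), or `ags`; optional
#'   `exclude_clades`, `reference_pp1`, `reference_ppz`, `motifs` (named list
#'   of column vectors with a `reference` id), `logo_columns`, `logo_group`,
#'   `seed`, plus any [conservation_config()] fields under `conservation`.
#' @param out Output directory (created if needed).
#' @return Invisibly, named vector of written file paths.
#' @export
run_conservation <- function(config, out) {
  config <- .load_config(config)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  hdr <- .provenance_header(config[setdiff(names(config), "ags")],
                            config$seed %||% NA)

  ags <- if (!is.null(config$ags)) config$ags else {
    aligned_group_set(read_fasta(config$alignment, aligned = TRUE),
                      read_labels(config$labels))
  }
  cfg_args <- config$conservation %||% list()
  cfg <- do.call(conservation_config, cfg_args)
  written <- character(0)

  # conserved counts, full set and with each exclusion applied
  exclusions <- config$exclude_clades %||% character(0)
  count_rows <- list()
  for (g in c("PP1", "PPZ")) {
    count_rows[[length(count_rows) + 1L]] <- data.frame(
      group = g, excluded = "none",
      n_conserved = length(conserved_positions(ags, g, cfg)),
      stringsAsFactors = FALSE)
  }
  if (length(exclusions)) {
    cfg_ex <- cfg; cfg_ex$exclude_clades <- exclusions
    for (g in c("PP1", "PPZ")) {
      count_rows[[length(count_rows) + 1L]] <- data.frame(
        group = g, excluded = paste(exclusions, collapse = ","),
        n_conserved = length(conserved_positions(ags, g, cfg_ex)),
        stringsAsFactors = FALSE)
    }
  }
  p <- file.path(out, "conserved_counts.tsv")
  .write_report(do.call(rbind, count_rows), p, hdr)
  written["conserved_counts"] <- p

  profiles <- column_profiles(ags, cfg)
  clade_prof <- clade_column_profiles(ags, cfg)
  classes <- classify_columns(profiles, cfg, clade_prof)
  for (ref_key in c("reference_pp1", "reference_ppz")) {
    ref <- config[[ref_key]]
    colname <- if (ref_key == "reference_pp1") "pp1_ref_pos" else "ppz_ref_pos"
    classes[[colname]] <- if (is.null(ref)) NA_integer_ else
      vapply(classes$column, function(j) {
        v <- column_to_residue(ags, j, ref)
        if (is.na(v)) NA_integer_ else v
      }, integer(1))
  }
  p <- file.path(out, "class_table.tsv")
  .write_report(classes, p, hdr)
  written["class_table"] <- p

  p <- file.path(out, "charge_swaps.tsv")
  .write_report(charge_change_scan(profiles, cfg), p, hdr)
  written["charge_swaps"] <- p

  if (!is.null(config$motifs)) {
    motif_rows <- list()
    for (m in names(config$motifs)) {
      spec <- config$motifs[[m]]
      rep <- motif_report(ags, spec$columns, spec$reference, cfg)
      rep$motif <- m
      motif_rows[[m]] <- rep
    }
    p <- file.path(out, "motif_report.tsv")
    .write_report(do.call(rbind, motif_rows), p, hdr)
    written["motif_report"] <- p
  }

  if (!is.null(config$logo_columns)) {
    g <- config$logo_group %||% "PPZ"
    lm <- shannon_logo_matrix(ags, g, config$logo_columns)
    df <- data.frame(residue = rownames(lm), lm, check.names = FALSE)
    p <- file.path(out, "logo_matrix.tsv")
    .write_report(df, p, hdr)
    written["logo_matrix"] <- p
  }

  for (g in c("PP1", "PPZ")) {
    m <- pairwise_identity(ags, g)
    df <- data.frame(id = rownames(m), m, check.names = FALSE)
    p <- file.path(out, sprintf("identity_%s.tsv", g))
    .write_report(df, p, hdr)
    written[paste0("identity_", g)] <- p
  }

  ident_all <- pairwise_identity(ags, NULL)
  d <- 1 - ident_all
  d[is.na(d)] <- 1
  diag(d) <- 0
  nwk <- nj_tree(d)
  p <- file.path(out, "tree.nwk")
  writeLines(nwk, p)
  written["tree"] <- p

  invisible(written)
}

#' Run the cross-link arm end to end
#'
#' Reads an MGF and a two-protein FASTA (or takes objects directly), runs
#' [search_crosslinks()], and writes the filter stage counts, the full
#' candidate table, the approved cross-links and a contact-map edge list.
#' Stage counts are monotone non-increasing along the filter chain. With
#' zero scans surviving, a warning is raised and empty-but-valid outputs are
#' still written.
#'
#' @param config List (or JSON path): `mgf` path or `scans`; `fasta` path
#'   (two records) or `prot_a`/`prot_b`; optional `construct_offset_a`
#'   (trim position applied to protein A), [xlms_config()] fields under
#'   `xlms`, `seed`.
#' @param out Output directory.
#' @return Invisibly, named vector of written paths.
#' @export
run_xlms <- function(config, out) {
  config <- .load_config(config)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  keep <- setdiff(names(config), c("scans", "prot_a", "prot_b"))
  hdr <- .provenance_header(config[keep], config$seed %||% NA)

  scans <- if (!is.null(config$scans)) config$scans else read_mgf(config$mgf)
  if (!is.null(config$fasta)) {
    recs <- read_fasta(config$fasta)
    if (length(recs) != 2L) stop("xlms fasta must hold exactly two proteins")
    prot_a <- recs[[1]]; prot_b <- recs[[2]]
  } else {
    prot_a <- config$prot_a; prot_b <- config$prot_b
  }
  if (!is.null(config$construct_offset_a)) {
    prot_a <- trim_to_domain(prot_a, config$construct_offset_a)
  }
  xcfg <- do.call(xlms_config, config$xlms %||% list())

  results <- search_crosslinks(scans, prot_a, prot_b, xcfg)
  counts <- attr(results, "counts")
  if (counts[["after_linker"]] == 0L) {
    warning("no scans survive filtering; writing empty outputs")
  }
  written <- character(0)

  p <- file.path(out, "filter_counts.tsv")
  .write_report(data.frame(stage = names(counts), count = unname(counts)),
                p, hdr)
  written["filter_counts"] <- p

  empty_cols <- data.frame(scan_title = character(0), type = character(0),
                           stringsAsFactors = FALSE)
  p <- file.path(out, "candidates.tsv")
  .write_report(if (nrow(results)) results else empty_cols, p, hdr)
  written["candidates"] <- p

  approved <- if (nrow(results)) {
    results[results$approved & results$type == "crosslink", , drop = FALSE]
  } else empty_cols
  p <- file.path(out, "approved.tsv")
  .write_report(approved, p, hdr)
  written["approved"] <- p

  if (nrow(approved)) {
    recs <- records_from_results(results, prot_a$id, prot_b$id)
    lens <- stats::setNames(
      c(prot_a$offset + seq_length(prot_a) - 1L,
        prot_b$offset + seq_length(prot_b) - 1L),
      c(prot_a$id, prot_b$id))
    edges <- export_map(recs, lens)$edges
  } else {
    edges <- data.frame(prot_a = character(0), site_a = integer(0),
                        prot_b = character(0), site_b = integer(0),
                        ambiguous = logical(0), weight = numeric(0),
                        record = integer(0), stringsAsFactors = FALSE)
  }
  p <- file.path(out, "contact_edges.tsv")
  .write_report(edges, p, hdr)
  written["contact_edges"] <- p

  invisible(written)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Command-line entry point
#'
#' Subcommands: `simulate-family`, `simulate-xlms`, `conservation`, `xlms`,
#' `map`. Flags: `--config <json>`, `--out <dir>`, `--seed <int>`. Returns 0
#' on success, 2 on validation error (the wrapper script passes this to
#' `quit(status=)`).
#'
#' @param args Character vector of CLI arguments (default: `commandArgs`).
#' @return Integer exit status, invisibly.
#' @export
ppz_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: ppzcompare <simulate-family|simulate-xlms|conservation|xlms|map>",
    "--config FILE --out DIR [--seed N]")
  if (!length(args)) { message(usage); return(invisible(2L)) }
  cmd <- args[1]
  opt <- list(config = NULL, out = ".", seed = 1L)
  i <- 2L
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (!key %in% names(opt) || i == length(args)) {
      message(usage); return(invisible(2L))
    }
    opt[[key]] <- if (key == "seed") as.integer(args[i + 1L]) else args[i + 1L]
    i <- i + 2L
  }
  status <- tryCatch({
    switch(cmd,
      "simulate-family" = {
        cfg_extra <- if (!is.null(opt$config)) .load_config(opt$config) else list()
        cfg_extra$seed <- opt$seed
        cfg <- do.call(family_sim_config, cfg_extra)
        sim <- simulate_family(cfg)
        dir.create(opt$out, showWarnings = FALSE, recursive = TRUE)
        write_fasta(sim$ags$records, file.path(opt$out, "family.fasta"))
        utils::write.table(sim$ags$labels, file.path(opt$out, "labels.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(sim$truth, file.path(opt$out, "truth.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        0L
      },
      "simulate-xlms" = {
        cfg_extra <- if (!is.null(opt$config)) .load_config(opt$config) else list()
        cfg_extra$seed <- opt$seed
        cfg <- do.call(xlms_sim_config, cfg_extra)
        sim <- simulate_xlms(cfg)
        dir.create(opt$out, showWarnings = FALSE, recursive = TRUE)
        write_mgf(sim$scans, file.path(opt$out, "spectra.mgf"))
        write_fasta(list(cfg$prot_a, cfg$prot_b),
                    file.path(opt$out, "proteins.fasta"))
        utils::write.table(sim$truth, file.path(opt$out, "truth.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        0L
      },
      "conservation" = { run_conservation(opt$config, opt$out); 0L },
      "xlms" = { run_xlms(opt$config, opt$out); 0L },
      "map" = {
        cfg <- .load_config(opt$config)
        recs <- parse_xl_table(cfg$table, cfg$prot_a %||% "Ppz1",
                               cfg$prot_b %||% "Hal3",
                               cfg$offset_a %||% 0L)
        dir.create(opt$out, showWarnings = FALSE, recursive = TRUE)
        lens <- unlist(cfg$lengths)
        em <- export_map(recs, lens)
        utils::write.table(em$edges, file.path(opt$out, "edges.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        0L
      },
      { message(usage); 2L })
  }, error = function(e) { message("error: ", conditionMessage(e)); 2L })
  invisible(status)
}
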