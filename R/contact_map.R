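## Bidimensional inter-protein contact mapping from validated cross-links or
## a Table-2-style TSV: intra/inter classification, ambiguous-site handling,
## region annotation and link-fraction statistics.

.xl_record <- function(prot_a, sites_a, prot_b, sites_b, evidence = NA_character_) {
  structure(list(prot_a = prot_a, sites_a = sort(as.integer(sites_a)),
                 prot_b = prot_b, sites_b = sort(as.integer(sites_b)),
                 evidence = evidence),
            class = "xl_record")
}

#' Parse a cross-link site table
#'
#' Reads a two-column TSV in the published dialect: column 1 holds the first
#' protein's lysine position, optionally `a/b` for ambiguous site pairs the
#' fragmentation spectra cannot distinguish; column 2 holds a comma-separated
#' list of partner positions, each expanding to its own record. An optional
#' `offset_a` converts construct numbering (e.g. a deletion construct) to
#' full-length coordinates on ingest.
#'
#' @param path TSV path (optionally with a header line; `#` comments
#'   ignored).
#' @param prot_a,prot_b Protein identifiers for the two columns.
#' @param offset_a,offset_b Added to every parsed site of the respective
#'   protein (default 0: sites already full-length).
#' @return List of `xl_record`s.
#' @export
parse_xl_table <- function(path, prot_a = "Ppz1", prot_b = "Hal3",
                           offset_a = 0L, offset_b = 0L) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  records <- list()
  for (k in seq_along(lines)) {
    parts <- strsplit(lines[k], "\t")[[1]]
    if (length(parts) < 2L) stop("row ", k, ": expected 2 tab-separated columns")
    if (k == 1L && !grepl("^[0-9]", trimws(parts[1]))) next  # header
    parse_sites <- function(txt, sep, row) {
      vals <- trimws(strsplit(txt, sep)[[1]])
      num <- suppressWarnings(as.integer(vals))
      if (anyNA(num)) stop("row ", row, ": non-numeric site '",
                           vals[which(is.na(num))[1]], "'")
      num
    }
    sites_a <- parse_sites(parts[1], "/", k) + as.integer(offset_a)
    partners <- parse_sites(parts[2], ",", k) + as.integer(offset_b)
    for (p in partners) {
      records[[length(records) + 1L]] <-
        .xl_record(prot_a, sites_a, prot_b, p)
    }
  }
  records
}

#' Build cross-link records from an approved search-result table
#'
#' @param results `data.frame` from [search_crosslinks()]; only approved
#'   cross-link rows are used.
#' @param prot_a,prot_b Protein identifiers.
#' @return List of `xl_record`s.
#' @export
records_from_results <- function(results, prot_a, prot_b) {
  rows <- results[results$type == "crosslink" & results$approved, , drop = FALSE]
  lapply(seq_len(nrow(rows)), function(i) {
    .xl_record(prot_a, rows$site_a[i], prot_b, rows$site_b[i],
               evidence = rows$scan_title[i])
  })
}

#' Tag records intra/inter
#'
#' @param records List of `xl_record`s.
#' @return The records, each gaining a `type` field (`intra` iff both
#'   proteins equal).
#' @export
classify_links <- function(records) {
  lapply(records, function(r) {
    r$type <- if (r$prot_a == r$prot_b) "intra" else "inter"
    r
  })
}

#' Link-type proportions
#'
#' @param records Non-empty list of `xl_record`s.
#' @return Named numeric vector of proportions over `intra-<protein>` and
#'   `inter`; sums to 1.
#' @export
fraction_by_type <- function(records) {
  if (!length(records)) stop("no records")
  labs <- vapply(records, function(r) {
    if (r$prot_a == r$prot_b) paste0("intra-", r$prot_a) else "inter"
  }, character(1))
  table(labs) / length(labs)
}

#' Define a region scheme
#'
#' Named half-open intervals `[start, end)` in full-length coordinates per
#' protein, e.g. an N-terminal extension versus thirds of a conserved domain.
#'
#' @param ... Per-protein `data.frame`s with columns name, start, end, passed
#'   as `ProteinId = df`.
#' @return Named list of class `region_scheme`.
#' @export
region_scheme <- function(...) {
  sch <- list(...)
  for (p in names(sch)) {
    df <- sch[[p]]
    stopifnot(all(c("name", "start", "end") %in% names(df)))
    if (anyDuplicated(df$name)) stop("duplicate region names for ", p)
  }
  structure(sch, class = "region_scheme")
}

.region_of <- function(scheme, prot, site) {
  df <- scheme[[prot]]
  if (is.null(df)) stop("no regions defined for protein ", prot)
  hit <- which(site >= df$start & site < df$end)
  if (!length(hit)) stop("site ", site, " of ", prot, " outside every region")
  df$name[hit[1]]
}

#' Per-region-pair link counts with fractional ambiguity
#'
#' Each record contributes a total weight of 1, split uniformly over the
#' members of its ambiguity sets (1/|sitesA| x 1/|sitesB| per member pair),
#' so totals over all cells equal the record count.
#'
#' @param records List of `xl_record`s.
#' @param scheme A `region_scheme` covering all sites.
#' @return `data.frame`: region_a, region_b, count.
#' @export
region_counts <- function(records, scheme) {
  acc <- list()
  for (r in records) {
    wa <- 1 / length(r$sites_a)
    wb <- 1 / length(r$sites_b)
    for (sa in r$sites_a) {
      ra <- .region_of(scheme, r$prot_a, sa)
      for (sb in r$sites_b) {
        rb <- .region_of(scheme, r$prot_b, sb)
        key <- paste(ra, rb, sep = "\t")
        acc[[key]] <- (if (is.null(acc[[key]])) 0 else acc[[key]]) + wa * wb
      }
    }
  }
  if (!length(acc)) {
    return(data.frame(region_a = character(0), region_b = character(0),
                      count = numeric(0), stringsAsFactors = FALSE))
  }
  keys <- sort(names(acc))
  parts <- do.call(rbind, strsplit(keys, "\t"))
  data.frame(region_a = parts[, 1], region_b = parts[, 2],
             count = unname(unlist(acc[keys])), stringsAsFactors = FALSE)
}

#' Export records as an edge list and residue-keyed incidence matrix
#'
#' Ambiguous records expand to one edge per member site, flagged `ambiguous`;
#' in the incidence matrix each edge carries weight 1/(|sitesA| x |sitesB|)
#' so the matrix total equals the record count. Edges are ordered by
#' (site_a, site_b) for deterministic output.
#'
#' @param records List of `xl_record`s.
#' @param lengths Named integer vector of protein lengths (full-length).
#' @return List with `edges` (`data.frame`: prot_a, site_a, prot_b, site_b,
#'   ambiguous, weight, record) and `matrix` (dense numeric,
#'   rows = first protein's residues, cols = second protein's).
#' @export
export_map <- function(records, lengths) {
  prots <- names(lengths)
  if (length(prots) < 1L) stop("lengths must be a named vector")
  rows <- list()
  for (i in seq_along(records)) {
    r <- records[[i]]
    amb <- length(r$sites_a) > 1L || length(r$sites_b) > 1L
    w <- 1 / (length(r$sites_a) * length(r$sites_b))
    for (sa in r$sites_a) for (sb in r$sites_b) {
      rows[[length(rows) + 1L]] <- data.frame(
        prot_a = r$prot_a, site_a = sa, prot_b = r$prot_b, site_b = sb,
        ambiguous = amb, weight = w, record = i, stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(rows)) {
    e <- do.call(rbind, rows)
    e[order(e$site_a, e$site_b, e$record), , drop = FALSE]
  } else {
    data.frame(prot_a = character(0), site_a = integer(0),
               prot_b = character(0), site_b = integer(0),
               ambiguous = logical(0), weight = numeric(0),
               record = integer(0), stringsAsFactors = FALSE)
  }
  pa <- if (length(records)) records[[1]]$prot_a else prots[1]
  pb <- if (length(records)) records[[1]]$prot_b else prots[min(2, length(prots))]
  mat <- matrix(0, nrow = lengths[[pa]], ncol = lengths[[pb]])
  if (nrow(edges)) {
    for (k in seq_len(nrow(edges))) {
      mat[edges$site_a[k], edges$site_b[k]] <-
        mat[edges$site_a[k], edges$site_b[k]] + edges$weight[k]
    }
  }
  list(edges = edges, matrix = mat)
}
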