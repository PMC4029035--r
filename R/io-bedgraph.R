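#' Default track colors
#'
#' Hex colors used for exported BED9 `itemRgb` fields. The green
#' `unlabeled` state marks profiles with no copy-number annotations; black
#' `conflict` marks segments overlapped by annotations of different states
#' and flags them for correction. The remaining colors are a fixed,
#' documented palette.
#'
#' @return named character vector of hex colors for the five copy states,
#'   `unlabeled`, `conflict`, and the two breakpoint-annotation labels.
#' @export
copy_state_palette <- function() {
  c(
    deletion = "#1B127D", loss = "#4656A8", normal = "#D0D0D0",
    gain = "#C14A2A", amplification = "#7B0711",
    unlabeled = "#2CA02C", conflict = "#000000",
    "0breakpoints" = "#F6F4BF", "1breakpoint" = "#FF7D7D"
  )
}

hex_to_rgb <- function(hex) {
  m <- grDevices::col2rgb(hex)
  paste(m[1L, ], m[2L, ], m[3L, ], sep = ",")
}

#' Parse the track header line of an uploaded bedGraph
#'
#' The header must carry the `db` variable (genome build, e.g. `db=hg19`);
#' `maxSegments` (per-chromosome cap on the initially displayed model)
#' defaults to 20 and `share` to `private` when absent. A bare domain such
#' as `share=curie.fr` maps to the `domain:curie.fr` variant. Key order is
#' irrelevant; unknown keys (e.g. `type=bedGraph`) are ignored.
#'
#' @param line the header line, beginning with the `track` keyword.
#' @return an `upload_meta` list: `genome_build`, `max_segments`, `share`.
#' @export
parse_track_header <- function(line) {
  tokens <- strsplit(trimws(line), "[ \t]+")[[1L]]
  if (length(tokens) == 0L || tokens[1L] != "track") {
    stop("track header must begin with the 'track' keyword")
  }
  kv <- tokens[-1L]
  bad <- !grepl("^[^=]+=[^=]*$", kv)
  if (any(bad)) stop(sprintf("malformed key=value pair: '%s'", kv[bad][1L]))
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  if (anyDuplicated(keys)) stop("duplicate keys in track header")
  get1 <- function(k) if (k %in% keys) vals[keys == k] else NULL
  db <- get1("db")
  if (is.null(db) || !nzchar(db)) stop("track header is missing the required db variable")
  ms <- get1("maxSegments")
  max_segments <- if (is.null(ms)) 20L else suppressWarnings(as.integer(ms))
  if (is.na(max_segments) || max_segments < 1L) {
    stop("maxSegments must be a positive integer")
  }
  share <- get1("share") %||% "private"
  if (!share %in% c("public", "private")) {
    share <- sub("^domain:", "", share)
    if (!nzchar(share)) stop("empty share domain")
    share <- paste0("domain:", share)
  }
  structure(
    list(genome_build = db, max_segments = max_segments, share = share),
    class = "upload_meta"
  )
}

#' Read a probe bedGraph into a profile
#'
#' Accepts a plain or gzipped four-column UCSC bedGraph whose first
#' non-comment line is the track header of [parse_track_header()]. Probes
#' are grouped by chromosome and sorted by start, so input line order is
#' irrelevant; start coordinates must be strictly increasing within a
#' chromosome after sorting (duplicates are rejected). Coordinates are
#' 0-based half-open; the probe's start coordinate is its position for all
#' downstream modeling.
#'
#' @param source path to a bedGraph file (`.gz` handled transparently) or a
#'   readable connection.
#' @return a `profile`: list with `meta` (an `upload_meta`) and
#'   `chromosomes` (named list, each a data.frame `start`/`end`/`logratio`
#'   sorted by start).
#' @export
read_probes <- function(source) {
  lines <- if (inherits(source, "connection")) readLines(source) else {
    con <- gzfile(source)
    on.exit(close(con))
    readLines(con)
  }
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") & !startsWith(lines, "browser")]
  if (length(lines) == 0L || !startsWith(lines[1L], "track")) {
    stop("first non-comment line must be a track header")
  }
  meta <- parse_track_header(lines[1L])
  body <- lines[-1L]
  if (length(body) == 0L) stop("no probe records")
  fields <- strsplit(body, "[ \t]+")
  nf <- lengths(fields)
  if (any(nf != 4L)) {
    stop(sprintf("bedGraph data lines must have 4 columns (line %d has %d)",
                 which(nf != 4L)[1L] + 1L, nf[nf != 4L][1L]))
  }
  m <- matrix(unlist(fields), ncol = 4L, byrow = TRUE)
  start <- suppressWarnings(as.numeric(m[, 2L]))
  end <- suppressWarnings(as.numeric(m[, 3L]))
  logratio <- suppressWarnings(as.numeric(m[, 4L]))
  if (anyNA(start) || anyNA(end)) stop("non-numeric coordinate")
  if (anyNA(logratio)) stop("non-numeric log ratio")
  if (any(start >= end)) stop("probe intervals must satisfy start < end")
  df <- data.frame(chrom = m[, 1L], start = start, end = end,
                   logratio = logratio, stringsAsFactors = FALSE)
  chromosomes <- lapply(split(df[c("start", "end", "logratio")], df$chrom), function(x) {
    x <- x[order(x$start), , drop = FALSE]
    if (anyDuplicated(x$start)) {
      stop("duplicate probe start position within a chromosome")
    }
    rownames(x) <- NULL
    x
  })
  chromosomes <- chromosomes[sort(names(chromosomes))]
  structure(list(meta = meta, chromosomes = chromosomes), class = "profile")
}

#' @export
print.profile <- function(x, ...) {
  cat(sprintf(
    "Copy-number profile (%s, maxSegments=%d, share=%s): %d chromosome(s), %d probes\n",
    x$meta$genome_build, x$meta$max_segments, x$meta$share,
    length(x$chromosomes), sum(vapply(x$chromosomes, nrow, integer(1)))
  ))
  invisible(x)
}

#' Read annotated regions from a BED4 file
#'
#' BED-like lines `chrom start end label`; the label vocabulary depends on
#' `kind`: `0breakpoints`/`1breakpoint` for breakpoint annotations, the
#' five ordered copy states for copy-number annotations. Regions are
#' returned sorted by chromosome and start. Overlapping breakpoint regions
#' on one chromosome are rejected: "exactly one change per region" is
#' ill-posed under overlap.
#'
#' @param source path to a BED4 file (or connection).
#' @param kind "breakpoint" or "copynumber".
#' @return data.frame with columns `chrom`, `start`, `end`, `label`.
#' @export
read_annotations <- function(source, kind = c("breakpoint", "copynumber")) {
  kind <- match.arg(kind)
  lines <- if (inherits(source, "connection")) readLines(source) else {
    con <- gzfile(source)
    on.exit(close(con))
    readLines(con)
  }
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") & !startsWith(lines, "track")]
  if (length(lines) == 0L) return(empty_annotations())
  fields <- strsplit(lines, "[ \t]+")
  if (any(lengths(fields) < 4L)) stop("annotation lines must have 4 columns")
  m <- t(vapply(fields, function(f) f[1:4], character(4)))
  anns <- data.frame(
    chrom = m[, 1L],
    start = suppressWarnings(as.numeric(m[, 2L])),
    end = suppressWarnings(as.numeric(m[, 3L])),
    label = m[, 4L],
    stringsAsFactors = FALSE
  )
  if (anyNA(anns$start) || anyNA(anns$end)) stop("non-numeric annotation coordinate")
  if (any(anns$start >= anns$end)) stop("annotation regions must satisfy start < end")
  vocab <- if (kind == "breakpoint") .bp_labels else copy_states()
  bad <- setdiff(unique(anns$label), vocab)
  if (length(bad)) {
    stop(sprintf("unknown %s annotation label(s): %s", kind, paste(bad, collapse = ", ")))
  }
  anns <- anns[order(anns$chrom, anns$start), , drop = FALSE]
  rownames(anns) <- NULL
  if (kind == "breakpoint") validate_breakpoint_annotations(anns)
  anns
}

fmt_num <- function(x) format(x, digits = 15, trim = TRUE, scientific = FALSE)

write_track_lines <- function(lines, path) {
  writeLines(lines, path)
  path
}

#' Write UCSC genome-browser tracks for a profile and its displayed models
#'
#' Writes five plain-text tracks to `outdir`, all 0-based half-open and
#' sorted within chromosome: probes as bedGraph (with the original track
#' header, so reading it back reproduces the profile), annotated regions
#' as BED9 with `itemRgb` colors, segment means as bedGraph, breakpoints
#' as BED, and per-segment copy state as BED9 colored by state.
#'
#' @param profile a `profile`.
#' @param displayed named list (chromosome -> `displayed_model`); every
#'   chromosome of the profile must be present.
#' @param bp_anns,cn_anns annotation data.frames (may be NULL/empty).
#' @param outdir output directory (created if needed).
#' @return character vector of the five written file paths.
#' @export
write_ucsc_tracks <- function(profile, displayed, bp_anns = NULL, cn_anns = NULL, outdir) {
  stopifnot(inherits(profile, "profile"))
  chroms <- names(profile$chromosomes)
  missing_d <- setdiff(chroms, names(displayed))
  if (length(missing_d)) {
    stop(sprintf("no displayed model for chromosome(s): %s", paste(missing_d, collapse = ", ")))
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  pal <- copy_state_palette()
  meta <- profile$meta
  share_out <- sub("^domain:", "", meta$share)
  header <- sprintf("track type=bedGraph db=%s maxSegments=%d share=%s",
                    meta$genome_build, meta$max_segments, share_out)

  probe_lines <- header
  seg_lines <- "track type=bedGraph name=segment_mean"
  bp_lines <- character(0)
  state_lines <- character(0)
  for (ch in chroms) {
    probes <- profile$chromosomes[[ch]]
    probe_lines <- c(probe_lines, sprintf(
      "%s\t%s\t%s\t%s", ch, fmt_num(probes$start), fmt_num(probes$end),
      fmt_num(probes$logratio)
    ))
    dm <- displayed[[ch]]
    spans <- dm$spans %||% segment_spans(dm$model, probes$start)
    seg_lines <- c(seg_lines, sprintf(
      "%s\t%d\t%d\t%s", ch, spans$start, spans$end, fmt_num(dm$model$segment_means)
    ))
    if (length(dm$breakpoints)) {
      bp_lines <- c(bp_lines, sprintf(
        "%s\t%d\t%d\tbreakpoint", ch, dm$breakpoints, dm$breakpoints + 1L
      ))
    }
    states <- dm$states %||% rep("unlabeled", dm$model$k)
    state_lines <- c(state_lines, sprintf(
      "%s\t%d\t%d\t%s\t0\t.\t%d\t%d\t%s",
      ch, spans$start, spans$end, states, spans$start, spans$end,
      hex_to_rgb(pal[states])
    ))
  }
  ann <- rbind(
    if (!is.null(bp_anns) && nrow(bp_anns)) bp_anns else NULL,
    if (!is.null(cn_anns) && nrow(cn_anns)) cn_anns else NULL
  )
  ann_lines <- character(0)
  if (!is.null(ann) && nrow(ann)) {
    ann <- ann[order(ann$chrom, ann$start), , drop = FALSE]
    ann_lines <- sprintf(
      "%s\t%d\t%d\t%s\t0\t.\t%d\t%d\t%s",
      ann$chrom, as.integer(ann$start), as.integer(ann$end), ann$label,
      as.integer(ann$start), as.integer(ann$end), hex_to_rgb(pal[ann$label])
    )
  }
  paths <- c(
    probes = write_track_lines(probe_lines, file.path(outdir, "probes.bedGraph")),
    annotations = write_track_lines(ann_lines, file.path(outdir, "annotations.bed")),
    segments = write_track_lines(seg_lines, file.path(outdir, "segments.bedGraph")),
    breakpoints = write_track_lines(bp_lines, file.path(outdir, "breakpoints.bed")),
    copy_states = write_track_lines(state_lines, file.path(outdir, "copy_states.bed"))
  )
  paths
}

#' Table of detected alterations
#'
#' One row per breakpoint and one row per segment whose called state is an
#' alteration (gain, loss, amplification or deletion); normal, unlabeled
#' and conflict segments are excluded.
#'
#' @param displayed named list (chromosome -> `displayed_model`) whose
#'   `spans` and `states` fields are filled.
#' @return data.frame with columns `chrom`, `start`, `end`, `type`.
#' @export
alteration_table <- function(displayed) {
  rows <- list()
  for (ch in names(displayed)) {
    dm <- displayed[[ch]]
    if (length(dm$breakpoints)) {
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch, start = dm$breakpoints, end = dm$breakpoints + 1L,
        type = "breakpoint", stringsAsFactors = FALSE
      )
    }
    states <- dm$states
    if (!is.null(states)) {
      alt <- which(states %in% c("gain", "loss", "amplification", "deletion"))
      if (length(alt)) {
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = ch, start = dm$spans$start[alt], end = dm$spans$end[alt],
          type = states[alt], stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), type = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
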