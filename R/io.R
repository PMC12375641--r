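#' Write a dose grid and its structure masks to a volumetric container
#'
#' One self-describing plain-text file per patient-condition: a header
#' (magic line, dims, spacing, origin, structure names), the dose values in
#' `%.17g` (lossless for IEEE doubles), and one 0/1 block per mask, all in
#' column-major voxel order. Atomic provenance: everything needed to rebuild
#' the grid and masks travels in one file.
#'
#' @param grid a [dose_grid()].
#' @param masks named list of [structure_mask()] congruent with `grid`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_volumetric <- function(grid, masks, path) {
  stopifnot(inherits(grid, "dose_grid"))
  for (m in masks) check_congruent(grid, m)
  d <- dim(grid$values)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "RBEVOL 1",
    paste("dims:", paste(d, collapse = " ")),
    paste("spacing_mm:", paste(sprintf("%.17g", grid$spacing), collapse = " ")),
    paste("origin_mm:", paste(sprintf("%.17g", grid$origin), collapse = " ")),
    paste("structures:", paste(names(masks), collapse = " ")),
    "DOSE_CGY"
  ), con)
  vals <- sprintf("%.17g", as.vector(grid$values))
  writeLines(vapply(split(vals, ceiling(seq_along(vals) / d[1])),
                    paste, character(1), collapse = " "), con)
  for (nm in names(masks)) {
    writeLines(paste("MASK", nm), con)
    bits <- as.integer(as.vector(masks[[nm]]$voxels))
    writeLines(vapply(split(bits, ceiling(seq_along(bits) / d[1])),
                      paste, character(1), collapse = ""), con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a volumetric container
#'
#' Inverse of [write_volumetric()]; the write-read round trip is
#' bit-identical. A truncated or malformed file raises an error rather than
#' returning partial data.
#'
#' @param path file written by [write_volumetric()].
#' @return list with `grid` (a [dose_grid()]) and `masks` (named list of
#'   [structure_mask()]).
#' @export
read_volumetric <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  fail <- function(what) stop(sprintf("%s: %s (corrupt or truncated file)",
                                      path, what))
  if (length(lines) < 7L || lines[1] != "RBEVOL 1") fail("bad magic header")
  hdr <- function(i, key) {
    if (!startsWith(lines[i], paste0(key, ":"))) fail(paste("missing", key))
    strsplit(trimws(sub(paste0(key, ":"), "", lines[i], fixed = TRUE)),
             "\\s+")[[1]]
  }
  dims <- as.integer(hdr(2, "dims"))
  spacing <- as.numeric(hdr(3, "spacing_mm"))
  origin <- as.numeric(hdr(4, "origin_mm"))
  structs <- hdr(5, "structures")
  if (lines[6] != "DOSE_CGY") fail("missing DOSE_CGY section")
  n_vox <- prod(dims)
  rows_per_block <- ceiling(n_vox / dims[1])
  i <- 7L
  dose_lines <- lines[i:(i + rows_per_block - 1L)]
  if (anyNA(dose_lines)) fail("dose section truncated")
  dose <- as.numeric(unlist(strsplit(dose_lines, " ", fixed = TRUE)))
  if (length(dose) != n_vox || anyNA(dose)) fail("dose section truncated")
  i <- i + rows_per_block
  vv <- prod(spacing) / 1000
  masks <- list()
  for (nm in structs) {
    if (i > length(lines) || lines[i] != paste("MASK", nm))
      fail(sprintf("missing MASK %s", nm))
    blk <- lines[(i + 1L):(i + rows_per_block)]
    if (anyNA(blk)) fail(sprintf("mask %s truncated", nm))
    bits <- as.integer(unlist(strsplit(paste(blk, collapse = ""), "",
                                       fixed = TRUE)))
    if (length(bits) != n_vox || anyNA(bits) || any(!bits %in% 0:1))
      fail(sprintf("mask %s truncated", nm))
    masks[[nm]] <- structure_mask(nm, array(bits == 1L, dims), vv)
    i <- i + rows_per_block + 1L
  }
  if (i > length(lines) || lines[i] != "END") fail("missing END marker")
  list(grid = dose_grid(array(dose, dims), spacing, origin), masks = masks)
}

#' Write differential DVHs as a CSV table
#'
#' Columns: `structure, bin_lo_cGy, bin_hi_cGy, volume_cc`. Doses are always
#' cGy and volumes cc, declared in the header names.
#'
#' @param dvhs list of (or a single) [differential_dvh()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_dvh_table <- function(dvhs, path) {
  if (inherits(dvhs, "dvh_diff")) dvhs <- list(dvhs)
  rows <- lapply(dvhs, function(d) {
    ne <- length(d$bin_edges)
    data.frame(structure = d$structure,
               bin_lo_cGy = sprintf("%.17g", d$bin_edges[-ne]),
               bin_hi_cGy = sprintf("%.17g", d$bin_edges[-1]),
               volume_cc = sprintf("%.17g", d$bin_volume),
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

# one Eclipse-style exported text block:
#   Structure: <name>
#   [Prescription Dose (cGy): <value>]
#   Total Volume (cc): <value>
#   <dose column header> <tab/spaces> <volume column header>
#   <numeric rows>
parse_eclipse_block <- function(block_lines, path, line0) {
  kv <- function(key) {
    hit <- grep(paste0("^", key, "\\s*[:(]"), block_lines, value = TRUE)
    if (length(hit) == 0L) return(NULL)
    as_num <- suppressWarnings(as.numeric(sub(".*:\\s*", "", hit[1])))
    as_num
  }
  name <- sub("^Structure\\s*:\\s*", "", grep("^Structure\\s*:", block_lines,
                                              value = TRUE)[1])
  total <- kv("Total Volume")
  rx <- kv("Prescription Dose")
  hdr_i <- grep("[Dd]ose", block_lines)
  hdr_i <- hdr_i[!grepl("^(Structure|Prescription)", block_lines[hdr_i])][1]
  if (is.na(hdr_i)) stop(sprintf("%s: block '%s' has no column header",
                                 path, name))
  hdr <- block_lines[hdr_i]
  cumulative <- grepl("Ratio of Total Structure Volume|Volume \\[|Volume \\(",
                      hdr) && !grepl("dVolume", hdr)
  pct_dose <- grepl("%\\s*of\\s*prescription|\\[%\\]", hdr, ignore.case = TRUE) &&
    grepl("[Dd]ose\\s*[\\[(]%", hdr)
  gy_dose <- grepl("[Dd]ose\\s*[\\[(]\\s*Gy", hdr)
  pct_vol <- grepl("Ratio of Total Structure Volume|Volume\\s*[\\[(]\\s*%", hdr)
  num_lines <- block_lines[(hdr_i + 1L):length(block_lines)]
  num_lines <- num_lines[nzchar(trimws(num_lines))]
  vals <- lapply(strsplit(trimws(num_lines), "\\s+"), as.numeric)
  if (any(lengths(vals) != 2L) || anyNA(unlist(vals)))
    stop(sprintf("%s: non-numeric row in block '%s'", path, name))
  tab <- do.call(rbind, vals)
  dose <- tab[, 1]; vol <- tab[, 2]
  if (pct_dose) {
    if (is.null(rx))
      stop(sprintf(
        "%s: block '%s' uses %% of prescription but has no Prescription Dose header",
        path, name))
    dose <- dose / 100 * rx
  } else if (gy_dose) {
    dose <- dose * 100
  }
  if (pct_vol) {
    if (is.null(total))
      stop(sprintf("%s: block '%s' uses %% volume but has no Total Volume header",
                   path, name))
    vol <- vol / 100 * total
  }
  if (cumulative) {
    if (any(diff(vol) > 1e-9 * max(vol)))
      stop(sprintf("%s: block '%s' cumulative volume increases at row %d",
                   path, name,
                   line0 + hdr_i + which(diff(vol) > 1e-9 * max(vol))[1] + 1L))
    cumulative_dvh(dose, vol, structure = name,
                   total_volume = total %||% max(vol))
  } else {
    # rows are (bin centre, bin volume) at constant width
    widths <- diff(dose)
    w <- if (length(widths)) stats::median(widths) else 1
    edges <- c(dose - w / 2, dose[length(dose)] + w / 2)
    if (edges[1] < 0) edges[1] <- 0
    differential_dvh(edges, vol, structure = name,
                     total_volume = total %||% sum(vol))
  }
}

#' Read tabular DVH files
#'
#' Two dialects: `"csv"` — the four-column differential format written by
#' [write_dvh_table()]; `"eclipse_text"` — TPS-export-style text blocks
#' (`Structure:` header, optional `Total Volume (cc):` and
#' `Prescription Dose (cGy):` lines, then a two-column dose/volume table).
#' Cumulative vs differential is detected from the column header; dose axes
#' in Gy or % of prescription and volume axes in % are normalised to cGy and
#' cc. Malformed input errors with file and offending structure/row, never
#' coerces.
#'
#' @param path input file.
#' @param dialect `"csv"` or `"eclipse_text"`.
#' @return named list of [differential_dvh()] / [cumulative_dvh()] objects,
#'   keyed by structure.
#' @export
read_dvh_table <- function(path, dialect = c("csv", "eclipse_text")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  if (dialect == "csv") {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("structure", "bin_lo_cGy", "bin_hi_cGy", "volume_cc")
    if (!all(need %in% names(tab)))
      stop(sprintf("%s: expected columns %s", path, paste(need, collapse = ", ")))
    out <- lapply(split(tab, tab$structure), function(s) {
      if (any(abs(s$bin_lo_cGy[-1] - s$bin_hi_cGy[-nrow(s)]) > 1e-9))
        stop(sprintf("%s: non-contiguous bins for structure '%s'",
                     path, s$structure[1]))
      differential_dvh(c(s$bin_lo_cGy, s$bin_hi_cGy[nrow(s)]), s$volume_cc,
                       structure = s$structure[1])
    })
    out[unique(tab$structure)]
  } else {
    lines <- readLines(path, warn = FALSE)
    starts <- grep("^Structure\\s*:", lines)
    if (length(starts) == 0L)
      stop(sprintf("%s: no 'Structure:' blocks found", path))
    ends <- c(starts[-1] - 1L, length(lines))
    out <- lapply(seq_along(starts), function(i)
      parse_eclipse_block(lines[starts[i]:ends[i]], path, starts[i] - 1L))
    names(out) <- vapply(out, `[[`, character(1), "structure")
    out
  }
}

#' Write an outcome table as tidy CSV
#'
#' @param outcomes an `outcome_table` from [evaluate_outcomes()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_outcome_table <- function(outcomes, path) {
  utils::write.csv(outcomes, path, row.names = FALSE)
  invisible(path)
}

#' Write comparison results as tidy CSV
#'
#' One row per metric for the omnibus test plus one row per post-hoc pair.
#'
#' @param comparisons result of [compare_cohort()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_comparison_table <- function(comparisons, path) {
  rows <- lapply(comparisons, function(cr) {
    omni <- data.frame(metric = cr$metric, test = "friedman", pair = "",
                       estimate = NA_real_, statistic = cr$friedman_stat,
                       raw_p = cr$friedman_p, adjusted_p = cr$friedman_p,
                       stars = star_label(cr$friedman_p),
                       omnibus_significant = cr$omnibus_significant,
                       stringsAsFactors = FALSE)
    ph <- data.frame(metric = cr$metric, test = "dunnett",
                     pair = cr$posthoc$pair, estimate = cr$posthoc$estimate,
                     statistic = cr$posthoc$t, raw_p = cr$posthoc$raw_p,
                     adjusted_p = cr$posthoc$adjusted_p,
                     stars = cr$posthoc$stars,
                     omnibus_significant = cr$omnibus_significant,
                     stringsAsFactors = FALSE)
    rbind(omni, ph)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
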