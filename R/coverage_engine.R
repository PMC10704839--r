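# Per-patient coverage: WIG masks -> 21-bin per-gene coverage tensor.
#
# A covered genomic position counts as 1 site, split into thirds over its 3
# alternate alleles; each third lands in the (zone, category) bin of that
# allele's consequence. Positions not reported in a patient's WIG are treated
# as fully covered; a patient with no WIG at all is fully covered everywhere.
# Per gene this yields 3 zones x 6 categories = 18 base bins plus the
# category-7 (indel/null) bin per zone, which equals the sum of categories
# 1-6 in that zone: 21 bins. The coverage "total" slot follows the same
# sum-over-1..6 convention.

#' Parse a WIG coverage/callability track
#'
#' Supports `fixedStep` and `variableStep` dialects. Positions whose value
#' exceeds `covered_min` enter the covered set; all reported positions enter
#' the reported set (unreported positions are treated as covered downstream).
#'
#' @param path WIG file path, or a character vector of WIG lines.
#' @param covered_min a position is covered iff value > `covered_min`
#'   (default 0; the sources encode presence/absence callable masks).
#' @return a `coverage_mask`: list with per-chromosome IRanges `covered` and
#'   `reported`, plus the threshold used.
#' @export
parse_wig <- function(path, covered_min = 0) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path) else as.character(path)
  covered <- list()
  reported <- list()
  chrom <- NULL; mode <- NULL; at <- NA_integer_; step <- 1L; span <- 1L

  push <- function(store, chrom, pos, w) {
    if (length(pos) == 0L) return(store)
    ir <- IRanges::IRanges(pos, width = w)
    store[[chrom]] <- if (is.null(store[[chrom]])) ir else c(store[[chrom]], ir)
    store
  }
  hdr_field <- function(line, key, lineno, required = TRUE) {
    m <- regmatches(line, regexpr(paste0(key, "=\\S+"), line))
    if (length(m) == 0L) {
      if (required) stop_synsig("malformed WIG header at line %d: missing %s=",
                                lineno, key, class = "synsig_parse_error")
      return(NA_character_)
    }
    sub(paste0(key, "="), "", m)
  }

  pos_buf <- integer(0); val_buf <- numeric(0)
  flush <- function() {
    if (length(pos_buf) == 0L) return()
    keep <- rep(pos_buf, each = span) + rep.int(seq_len(span) - 1L, length(pos_buf))
    vals <- rep(val_buf, each = span)
    reported <<- push(reported, chrom, keep, 1L)
    covered <<- push(covered, chrom, keep[vals > covered_min], 1L)
    pos_buf <<- integer(0); val_buf <<- numeric(0)
  }

  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (line == "" || startsWith(line, "#") || startsWith(line, "track")) next
    if (startsWith(line, "fixedStep")) {
      flush()
      mode <- "fixed"
      chrom <- norm_chrom(hdr_field(line, "chrom", i))
      at <- suppressWarnings(as.integer(hdr_field(line, "start", i)))
      if (is.na(at)) stop_synsig("malformed WIG header at line %d: bad start=",
                                 i, class = "synsig_parse_error")
      step <- suppressWarnings(as.integer(hdr_field(line, "step", i, required = FALSE)))
      if (is.na(step)) step <- 1L
      span <- suppressWarnings(as.integer(hdr_field(line, "span", i, required = FALSE)))
      if (is.na(span)) span <- 1L
    } else if (startsWith(line, "variableStep")) {
      flush()
      mode <- "variable"
      chrom <- norm_chrom(hdr_field(line, "chrom", i))
      span <- suppressWarnings(as.integer(hdr_field(line, "span", i, required = FALSE)))
      if (is.na(span)) span <- 1L
    } else {
      if (is.null(mode)) {
        stop_synsig("malformed WIG at line %d: data before any step header", i,
                    class = "synsig_parse_error")
      }
      if (mode == "fixed") {
        v <- suppressWarnings(as.numeric(line))
        if (is.na(v)) stop_synsig("malformed WIG value at line %d", i,
                                  class = "synsig_parse_error")
        pos_buf <- c(pos_buf, at); val_buf <- c(val_buf, v)
        at <- at + step
      } else {
        parts <- strsplit(line, "\\s+")[[1L]]
        if (length(parts) != 2L) {
          stop_synsig("malformed variableStep line %d: expected 'pos value'", i,
                      class = "synsig_parse_error")
        }
        p <- suppressWarnings(as.integer(parts[1L]))
        v <- suppressWarnings(as.numeric(parts[2L]))
        if (is.na(p) || is.na(v)) stop_synsig("malformed variableStep line %d", i,
                                              class = "synsig_parse_error")
        pos_buf <- c(pos_buf, p); val_buf <- c(val_buf, v)
      }
    }
  }
  flush()
  structure(list(covered = lapply(covered, IRanges::reduce),
                 reported = lapply(reported, IRanges::reduce),
                 covered_min = covered_min),
            class = "coverage_mask")
}

# Aggregate the site-effect table into the full-coverage bins, cached on the
# table so cohort-wide tensors reuse it.
full_coverage_bins <- function(site_effects, gene_ids) {
  cache <- attr(site_effects, "full_bins", exact = TRUE)
  if (!is.null(cache) && identical(attr(cache, "gene_ids"), gene_ids)) {
    return(cache)
  }
  agg <- as_dt(site_effects)[, .(w = sum(weight)),
                                     by = .(gene_id, category, zone)]
  slab <- array(0, dim = c(length(gene_ids), 8L, 3L),
                dimnames = list(gene_ids, CATEGORY_LEVELS, ZONES))
  agg <- agg[gene_id %in% gene_ids]
  slab[cbind(match(agg$gene_id, gene_ids), agg$category, agg$zone)] <- agg$w
  slab[, 7L, ] <- apply(slab[, 1:6, , drop = FALSE], c(1, 3), sum)
  slab[, 8L, ] <- slab[, 7L, ]  # coverage total slot: sum over categories 1-6
  data.table::setattr(slab, "gene_ids", gene_ids)
  data.table::setattr(site_effects, "full_bins", slab)
  slab
}

# positions (per chromosome) reported-but-not-covered for a mask
uncovered_positions <- function(mask) {
  out <- list()
  for (chrom in names(mask$reported)) {
    unc <- IRanges::setdiff(mask$reported[[chrom]],
                            mask$covered[[chrom]] %||% IRanges::IRanges())
    if (sum(IRanges::width(unc)) > 0L) {
      out[[chrom]] <- unlist(Map(seq.int, IRanges::start(unc), IRanges::end(unc)),
                             use.names = FALSE)
    }
  }
  out
}

#' Compute one patient's 21-bin coverage from a WIG mask
#'
#' @param mask a `coverage_mask` from [parse_wig()], or `NULL` for a patient
#'   with no WIG file (full coverage everywhere, with a warning).
#' @param site_effects table from [enumerate_site_effects()].
#' @param gene_ids gene axis (defaults to genes present in `site_effects`).
#' @return numeric array `[gene, category(1..7, total), zone]` in fractional
#'   site units (thirds).
#' @export
compute_patient_coverage <- function(mask, site_effects,
                                     gene_ids = unique(site_effects$gene_id)) {
  slab <- full_coverage_bins(site_effects, gene_ids)
  out <- slab + 0  # copy, drop cache attrs
  data.table::setattr(out, "gene_ids", NULL)
  if (is.null(mask)) {
    warning("patient has no WIG coverage file; assuming full coverage")
    return(out)
  }
  unc <- uncovered_positions(mask)
  if (length(unc) == 0L) return(out)
  se <- as_dt(site_effects)
  drop <- se[data.table::rbindlist(lapply(names(unc), function(ch) {
    data.table(chrom = ch, pos = unc[[ch]])
  })), on = c("chrom", "pos"), nomatch = NULL]
  if (nrow(drop) > 0L) {
    agg <- drop[gene_id %in% gene_ids, .(w = sum(weight)),
                by = .(gene_id, category, zone)]
    out[cbind(match(agg$gene_id, gene_ids), agg$category, agg$zone)] <-
      out[cbind(match(agg$gene_id, gene_ids), agg$category, agg$zone)] - agg$w
    out[, 7L, ] <- apply(out[, 1:6, , drop = FALSE], c(1, 3), sum)
    out[, 8L, ] <- out[, 7L, ]
  }
  out
}

#' Build the cohort coverage tensor
#'
#' @param site_effects table from [enumerate_site_effects()].
#' @param masks named list (by patient id) of `coverage_mask` objects;
#'   patients absent from the list get full coverage. `NULL` means full
#'   coverage for everyone.
#' @param patients character vector defining the patient axis.
#' @param gene_ids character vector defining the gene axis.
#' @return numeric array `[gene, category(1..7, total), patient, zone]`
#'   (class `coverage_tensor`).
#' @export
build_coverage_tensor <- function(site_effects, masks, patients,
                                  gene_ids = unique(site_effects$gene_id)) {
  tensor <- array(0, dim = c(length(gene_ids), 8L, length(patients), 3L),
                  dimnames = list(gene_ids, CATEGORY_LEVELS, patients, ZONES))
  full <- full_coverage_bins(site_effects, gene_ids) + 0
  for (pi in seq_along(patients)) {
    p <- patients[pi]
    if (!is.null(masks) && !is.null(masks[[p]])) {
      tensor[, , pi, ] <- compute_patient_coverage(masks[[p]], site_effects,
                                                   gene_ids)
    } else {
      tensor[, , pi, ] <- full
    }
  }
  class(tensor) <- c("coverage_tensor", class(tensor))
  tensor
}
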