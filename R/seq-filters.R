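## seq_filters module: coverage-based QC of sequencing-derived methylation.
## Two on-disk dialects are supported: a targeted short-read bedGraph
## (chrom, start, end, methylation %, methylated count, unmethylated count)
## and a long-read bedMethyl (BED9 + valid-coverage, percent-modified and
## modified-count columns, per strand).

#' Construct a coverage table
#'
#' @param sites data.frame with `chrom`, `start`, `end` (0-based half-open;
#'   CpG dinucleotides have `end = start + 2`).
#' @param meth,total sites x samples integer matrices of methylated and
#'   total read counts (NA = masked).
#' @param samples sample names.
#' @param platform platform label.
#' @param genome genome build.
#' @return object of class `coverage_table`.
#' @export
coverage_table <- function(sites, meth, total, samples,
                           platform = "short_read_panel",
                           genome = "GRCh38") {
  stopifnot(nrow(sites) == nrow(meth), identical(dim(meth), dim(total)),
            ncol(meth) == length(samples))
  if (any(meth > total, na.rm = TRUE) || any(meth < 0, na.rm = TRUE)) {
    stop("methylated counts must satisfy 0 <= methylated <= total")
  }
  structure(list(sites = sites, meth = meth, total = total,
                 samples = samples, platform = platform, genome = genome),
            class = "coverage_table")
}

#' Site identifiers ("chrom-start-end") of a coverage table
#' @param x a `coverage_table`.
#' @return character vector.
#' @export
site_ids <- function(x) {
  paste(x$sites$chrom, x$sites$start, x$sites$end, sep = "-")
}

#' @export
print.coverage_table <- function(x, ...) {
  cat("coverage_table:", nrow(x$sites), "sites x", length(x$samples),
      "samples (", x$platform, ",", x$genome, ")\n")
  invisible(x)
}

.read_one_coverage <- function(path, dialect) {
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- if (file.size(path) == 0L) data.table::data.table() else tryCatch(
    data.table::fread(path, header = FALSE, sep = "\t"),
    error = function(e) stop("failed to parse ", path, ": ",
                             conditionMessage(e)))
  if (nrow(dt) == 0L) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), meth = integer(0),
                      total = integer(0)))
  }
  if (dialect == "bedgraph_panel") {
    if (ncol(dt) < 6L) {
      stop("bedGraph dialect needs 6 columns in ", path)
    }
    meth <- as.integer(dt[[5L]])
    total <- meth + as.integer(dt[[6L]])
    out <- data.frame(chrom = as.character(dt[[1L]]),
                      start = as.integer(dt[[2L]]),
                      end = as.integer(dt[[3L]]),
                      meth = meth, total = total,
                      stringsAsFactors = FALSE)
  } else { # bedmethyl_long_read
    if (ncol(dt) < 11L) {
      stop("bedMethyl dialect needs >= 11 columns in ", path)
    }
    total <- as.integer(dt[[10L]])
    meth <- if (ncol(dt) >= 12L) as.integer(dt[[12L]]) else
      as.integer(round(total * as.numeric(dt[[11L]]) / 100))
    start <- as.integer(dt[[2L]])
    strand <- as.character(dt[[6L]])
    ## collapse the reverse-strand cytosine onto the forward-strand CpG
    start[strand == "-"] <- start[strand == "-"] - 1L
    out <- data.frame(chrom = as.character(dt[[1L]]), start = start,
                      meth = meth, total = total, stringsAsFactors = FALSE)
    out <- stats::aggregate(cbind(meth, total) ~ chrom + start, data = out,
                            FUN = sum)
    out$end <- out$start + 2L
    out <- out[, c("chrom", "start", "meth", "total", "end")]
  }
  bad <- which(is.na(out$start) | is.na(out$total) | out$total < 0 |
                 out$meth > out$total | out$meth < 0)
  if (length(bad)) {
    stop("malformed coverage line(s) in ", path, " (first at record ",
         bad[1], ")")
  }
  if (any(out$start > .Machine$integer.max - 2L, na.rm = TRUE)) {
    stop("coordinate overflow in ", path)
  }
  out[order(out$chrom, out$start),
      c("chrom", "start", "end", "meth", "total")]
}

#' Read per-sample coverage files and merge on genomic intervals
#'
#' @param paths named character vector of files (names = sample ids; file
#'   base names are used when unnamed).
#' @param dialect `"bedgraph_panel"` or `"bedmethyl_long_read"`.
#' @param genome genome build label.
#' @return a `coverage_table`; sites absent from a sample are NA-masked.
#' @export
read_coverage <- function(paths, dialect = c("bedgraph_panel",
                                             "bedmethyl_long_read"),
                          genome = "GRCh38") {
  dialect <- match.arg(dialect)
  samples <- names(paths) %||% sub("\\.[^.]*$", "", basename(paths))
  per <- lapply(paths, .read_one_coverage, dialect = dialect)
  keys <- unique(do.call(rbind, lapply(per, function(d)
    d[, c("chrom", "start", "end")])))
  keys <- keys[order(keys$chrom, keys$start), , drop = FALSE]
  rownames(keys) <- NULL
  key_id <- paste(keys$chrom, keys$start, sep = ":")
  n_sites <- nrow(keys)
  meth <- total <- matrix(NA_integer_, n_sites, length(paths),
                          dimnames = list(NULL, samples))
  for (s in seq_along(per)) {
    idx <- match(paste(per[[s]]$chrom, per[[s]]$start, sep = ":"), key_id)
    meth[idx, s] <- per[[s]]$meth
    total[idx, s] <- per[[s]]$total
  }
  platform <- if (dialect == "bedgraph_panel") "short_read_panel" else
    "long_read"
  coverage_table(keys, meth, total, samples, platform = platform,
                 genome = genome)
}

#' Write a coverage table in a canonical dialect
#'
#' One file per sample under `dir`; masked (NA) entries are omitted.
#' bedGraph: chrom, start, end, methylation %, methylated, unmethylated.
#' bedMethyl: BED9 (forward strand) plus valid coverage, percent modified,
#' modified and canonical counts. Writing then re-reading preserves counts
#' exactly, and re-writing a read canonical file is byte-identical.
#'
#' @param x a `coverage_table`.
#' @param dir output directory (created if needed).
#' @param dialect output dialect.
#' @return named vector of written paths, invisibly.
#' @export
write_coverage <- function(x, dir, dialect = c("bedgraph_panel",
                                               "bedmethyl_long_read")) {
  dialect <- match.arg(dialect)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (dialect == "bedgraph_panel") ".bedgraph" else ".bedmethyl"
  paths <- setNames(file.path(dir, paste0(x$samples, ext)), x$samples)
  for (s in seq_along(x$samples)) {
    ok <- !is.na(x$total[, s])
    m <- x$meth[ok, s]
    tt <- x$total[ok, s]
    pct <- ifelse(tt > 0, 100 * m / tt, 0)
    if (dialect == "bedgraph_panel") {
      lines <- sprintf("%s\t%d\t%d\t%.2f\t%d\t%d",
                       x$sites$chrom[ok], x$sites$start[ok],
                       x$sites$end[ok], pct, m, tt - m)
    } else {
      lines <- sprintf(
        "%s\t%d\t%d\tm\t%d\t+\t%d\t%d\t255,0,0\t%d\t%.2f\t%d\t%d",
        x$sites$chrom[ok], x$sites$start[ok], x$sites$end[ok],
        pmin(tt, 1000L), x$sites$start[ok], x$sites$end[ok], tt, pct, m,
        tt - m)
    }
    writeLines(lines, paths[s])
  }
  invisible(paths)
}

#' Read a BED file of masked intervals (e.g. C-to-T polymorphisms)
#' @param path BED3+ file.
#' @return data.frame with `chrom`, `start`, `end`.
#' @export
read_bed_mask <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  if (nrow(dt) == 0L) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0)))
  }
  data.frame(chrom = as.character(dt[[1L]]), start = as.integer(dt[[2L]]),
             end = as.integer(dt[[3L]]), stringsAsFactors = FALSE)
}

#' Coverage filter policy
#'
#' Defaults reproduce the published retention rules: minimal depth of
#' coverage 2, removal of sites beyond the 0.99 quantile of mean coverage,
#' removal of sites overlapping known C-to-T polymorphisms, and retention
#' of sites covered in at least 40 samples by 10+ reads (short-read panel)
#' or 5+ reads (long read).
#'
#' @param min_doc minimal per-entry depth of coverage.
#' @param high_coverage_quantile quantile of the per-site mean-coverage
#'   distribution above which sites are removed (strictly greater than).
#' @param snp_mask data.frame of BED intervals, or `NULL`.
#' @param min_samples minimum number of well-covered samples.
#' @param min_reads_platform per-sample read minimum for the retention
#'   step; defaults to 10 for the short-read panel and 5 for long read
#'   when `NULL`.
#' @return list of class `filter_policy`.
#' @export
filter_policy <- function(min_doc = 2L, high_coverage_quantile = 0.99,
                          snp_mask = NULL, min_samples = 40L,
                          min_reads_platform = NULL) {
  stopifnot(min_doc >= 1, high_coverage_quantile > 0,
            high_coverage_quantile < 1)
  structure(list(min_doc = as.integer(min_doc),
                 high_coverage_quantile = high_coverage_quantile,
                 snp_mask = snp_mask,
                 min_samples = as.integer(min_samples),
                 min_reads_platform = min_reads_platform),
            class = "filter_policy")
}

.overlaps_mask <- function(sites, mask) {
  if (is.null(mask) || nrow(mask) == 0L) return(rep(FALSE, nrow(sites)))
  hit <- rep(FALSE, nrow(sites))
  for (ch in unique(sites$chrom)) {
    si <- which(sites$chrom == ch)
    mi <- mask[mask$chrom == ch, , drop = FALSE]
    if (nrow(mi) == 0L) next
    for (k in seq_len(nrow(mi))) {
      hit[si] <- hit[si] |
        (sites$start[si] < mi$end[k] & sites$end[si] > mi$start[k])
    }
  }
  hit
}

#' Apply the stepwise coverage filters
#'
#' Steps, in order: (1) mask per-sample entries with coverage below
#' `min_doc` (a site whose entries are all masked is removed); (2) remove
#' sites whose cross-sample mean coverage is strictly greater than the
#' `high_coverage_quantile` quantile (type 7) of the per-site mean-coverage
#' distribution — ties at the quantile survive; (3) remove sites
#' intersecting the polymorphism mask; (4) retain sites covered in at
#' least `min_samples` samples by at least the platform read minimum.
#' The audit log records sites removed at each step; removals plus
#' survivors always equal the input site count.
#'
#' @param x a `coverage_table`.
#' @param policy a [filter_policy()].
#' @return list with the filtered `coverage_table` and an `audit`
#'   data.frame (step, sites_removed, sites_remaining).
#' @export
apply_filters <- function(x, policy = filter_policy()) {
  stopifnot(inherits(x, "coverage_table"), inherits(policy, "filter_policy"))
  n_samples <- length(x$samples)
  if (policy$min_samples > n_samples) {
    stop("min_samples (", policy$min_samples, ") exceeds sample count (",
         n_samples, ")")
  }
  min_reads <- policy$min_reads_platform %||%
    if (x$platform == "short_read_panel") 10L else 5L

  meth <- x$meth
  total <- x$total
  sites <- x$sites
  audit <- data.frame(step = character(0), sites_removed = integer(0),
                      sites_remaining = integer(0))
  log_step <- function(step, removed, remaining) {
    rbind(audit, data.frame(step = step, sites_removed = removed,
                            sites_remaining = remaining))
  }

  ## step 1: low-coverage masking
  mask1 <- !is.na(total) & total < policy$min_doc
  meth[mask1] <- NA_integer_
  total[mask1] <- NA_integer_
  alive <- rowSums(!is.na(total)) > 0L
  audit <- log_step("low_doc_mask", sum(!alive), sum(alive))
  sites <- sites[alive, , drop = FALSE]
  meth <- meth[alive, , drop = FALSE]
  total <- total[alive, , drop = FALSE]

  ## step 2: extreme high coverage (per-site mean over observed entries)
  mean_doc <- rowMeans(total, na.rm = TRUE)
  cutoff <- quantile(mean_doc, policy$high_coverage_quantile, type = 7,
                     names = FALSE)
  keep2 <- mean_doc <= cutoff
  audit <- log_step("high_coverage", sum(!keep2), sum(keep2))
  sites <- sites[keep2, , drop = FALSE]
  meth <- meth[keep2, , drop = FALSE]
  total <- total[keep2, , drop = FALSE]

  ## step 3: polymorphism mask
  hit <- .overlaps_mask(sites, policy$snp_mask)
  audit <- log_step("snp_mask", sum(hit), sum(!hit))
  sites <- sites[!hit, , drop = FALSE]
  meth <- meth[!hit, , drop = FALSE]
  total <- total[!hit, , drop = FALSE]

  ## step 4: cross-sample coverage retention
  well <- rowSums(!is.na(total) & total >= min_reads)
  keep4 <- well >= policy$min_samples
  audit <- log_step("min_sample_coverage", sum(!keep4), sum(keep4))
  sites <- sites[keep4, , drop = FALSE]
  meth <- meth[keep4, , drop = FALSE]
  total <- total[keep4, , drop = FALSE]

  filtered <- coverage_table(sites, meth, total, x$samples,
                             platform = x$platform, genome = x$genome)
  list(coverage = filtered, audit = audit)
}

#' Methylation fractions from a coverage table
#'
#' fraction = methylated / total per site and sample; masked entries (or
#' zero totals) propagate as NA, never as a division error. Rows are site
#' ids, columns samples; transposed to samples x sites for the EWAS.
#'
#' @param x a `coverage_table`.
#' @return samples x sites matrix of fractions with NA for masked entries.
#' @export
methylation_fraction <- function(x) {
  stopifnot(inherits(x, "coverage_table"))
  frac <- x$meth / ifelse(is.na(x$total) | x$total == 0, NA_real_,
                          x$total)
  dimnames(frac) <- list(site_ids(x), x$samples)
  t(frac)
}
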