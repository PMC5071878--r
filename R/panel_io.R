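#' Construct a genotype or haplotype panel
#'
#' A panel is a sample-by-SNP integer matrix. Diploid genotypes are coded
#' 0/1/2 (the number of minor alleles an individual carries at the SNP);
#' phased haplotypes are coded 0/1 (major/minor allele). Missing entries
#' carry the integer sentinel (default -1), which never collides with a
#' valid code.
#'
#' @param values integer matrix, rows = samples, columns = SNPs.
#' @param ploidy `"diploid_genotype"` (codes 0/1/2) or `"haplotype"` (0/1).
#' @param sample_ids character vector, one per row. Defaults to `s1, s2, ...`.
#' @param snp_ids character vector, one per column, unique within the panel.
#'   Defaults to `snp1, snp2, ...`.
#' @param missing_sentinel integer marking missing entries; must not be a
#'   valid code.
#' @return An object of class `genotype_panel`.
#' @export
genotype_panel <- function(values,
                           ploidy = c("diploid_genotype", "haplotype"),
                           sample_ids = NULL,
                           snp_ids = NULL,
                           missing_sentinel = -1L) {
  ploidy <- match.arg(ploidy)
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "integer"
  n <- nrow(values)
  m <- ncol(values)
  if (n == 0L || m == 0L) stop_ri("panel must have at least one sample and one SNP")
  sample_ids <- sample_ids %||% paste0("s", seq_len(n))
  snp_ids <- snp_ids %||% paste0("snp", seq_len(m))
  if (length(sample_ids) != n) stop_ri("sample_ids length must equal number of rows")
  if (length(snp_ids) != m) stop_ri("snp_ids length must equal number of columns")
  if (anyDuplicated(snp_ids)) stop_ri("snp_ids must be unique within a panel")
  codes <- valid_codes(ploidy)
  if (missing_sentinel %in% codes) {
    stop_ri("missing_sentinel collides with a valid ", ploidy, " code")
  }
  obs <- values != missing_sentinel
  bad <- obs & !(values %in% codes)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop_ri(sprintf(
      "invalid code %d at row %d (%s), column %d (%s) for ploidy %s",
      values[idx[1L], idx[2L]], idx[1L], sample_ids[idx[1L]],
      idx[2L], snp_ids[idx[2L]], ploidy
    ))
  }
  structure(
    list(
      values = values,
      ploidy = ploidy,
      missing_sentinel = as.integer(missing_sentinel),
      sample_ids = as.character(sample_ids),
      snp_ids = as.character(snp_ids)
    ),
    class = "genotype_panel"
  )
}

valid_codes <- function(ploidy) {
  if (ploidy == "haplotype") c(0L, 1L) else c(0L, 1L, 2L)
}

#' @export
print.genotype_panel <- function(x, ...) {
  n_miss <- sum(x$values == x$missing_sentinel)
  cat(sprintf(
    "genotype_panel: %d samples x %d SNPs (%s), %d missing (%.1f%%)\n",
    nrow(x$values), ncol(x$values), x$ploidy, n_miss,
    100 * n_miss / length(x$values)
  ))
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) dim(x$values)

#' Observation mask of a panel
#'
#' Logical matrix, `TRUE` where the panel entry is observed (not the missing
#' sentinel). This is the index set of known entries that the completion
#' models fit against.
#'
#' @param panel a [genotype_panel()].
#' @return logical matrix with the panel's shape.
#' @export
mask_from_panel <- function(panel) {
  stopifnot(inherits(panel, "genotype_panel"))
  obs <- panel$values != panel$missing_sentinel
  if (!any(obs)) stop_ri("panel has no observed entries")
  obs
}

#' Read a panel from delimited text
#'
#' Format: optional header line `#SNP id1 id2 ...`; one sample per data line,
#' first field the sample id, remaining fields codes 0/1/2 (or 0/1 for
#' haplotypes) or the missing token. Whitespace- or tab-delimited.
#'
#' @param path file path.
#' @inheritParams genotype_panel
#' @param missing_token textual token marking a missing entry (default `"?"`).
#' @return A [genotype_panel()].
#' @export
read_panel <- function(path,
                       ploidy = c("diploid_genotype", "haplotype"),
                       missing_token = "?") {
  ploidy <- match.arg(ploidy)
  if (!file.exists(path)) stop_ri("panel file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop_ri("no samples in panel file: ", path)
  snp_ids <- NULL
  if (startsWith(lines[1L], "#SNP")) {
    snp_ids <- strsplit(trimws(lines[1L]), "[ \t]+")[[1L]][-1L]
    lines <- lines[-1L]
  }
  if (length(lines) == 0L) stop_ri("no samples in panel file: ", path)
  fields <- strsplit(trimws(lines), "[ \t]+")
  widths <- lengths(fields)
  if (length(unique(widths)) != 1L) {
    stop_ri("ragged rows in ", path, ": line widths ", paste(unique(widths), collapse = ", "))
  }
  if (widths[1L] < 2L) stop_ri("each data line needs a sample id and at least one code")
  sample_ids <- vapply(fields, `[`, character(1L), 1L)
  m <- widths[1L] - 1L
  codes <- as.character(valid_codes(ploidy))
  values <- matrix(-1L, nrow = length(fields), ncol = m)
  for (i in seq_along(fields)) {
    toks <- fields[[i]][-1L]
    known <- toks %in% codes
    miss <- toks == missing_token
    if (any(!known & !miss)) {
      j <- which(!known & !miss)[1L]
      stop_ri(sprintf(
        "malformed token '%s' at row %d (%s), column %d in %s",
        toks[j], i, sample_ids[i], j, path
      ))
    }
    values[i, known] <- as.integer(toks[known])
  }
  genotype_panel(values, ploidy,
    sample_ids = sample_ids,
    snp_ids = snp_ids %||% paste0("snp", seq_len(m))
  )
}

#' Write a panel to delimited text
#'
#' Inverse of [read_panel()]: a written panel re-reads identically (values,
#' ids, sentinel positions).
#'
#' @inheritParams mask_from_panel
#' @param path destination file.
#' @param missing_token textual missing token to emit (default `"?"`).
#' @export
write_panel <- function(panel, path, missing_token = "?") {
  stopifnot(inherits(panel, "genotype_panel"))
  chr <- matrix(as.character(panel$values), nrow = nrow(panel$values))
  chr[panel$values == panel$missing_sentinel] <- missing_token
  lines <- c(
    paste(c("#SNP", panel$snp_ids), collapse = "\t"),
    vapply(seq_len(nrow(chr)), function(i) {
      paste(c(panel$sample_ids[i], chr[i, ]), collapse = "\t")
    }, character(1L))
  )
  ok <- tryCatch({
    writeLines(lines, path)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_ri("cannot write panel to ", path)
  invisible(path)
}

#' Read or write an observation mask as 0/1 text
#'
#' Same layout as the panel format: header `#SNP ...`, one row per sample,
#' tokens `1` (observed) / `0` (missing).
#'
#' @param path file path.
#' @return `read_mask`: logical matrix.
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop_ri("mask file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) && startsWith(lines[1L], "#SNP")) lines <- lines[-1L]
  if (!length(lines)) stop_ri("empty mask file: ", path)
  fields <- strsplit(trimws(lines), "[ \t]+")
  vals <- lapply(fields, function(f) f[-1L])
  if (length(unique(lengths(vals))) != 1L) stop_ri("ragged rows in mask file ", path)
  mat <- do.call(rbind, lapply(vals, function(v) {
    if (!all(v %in% c("0", "1"))) stop_ri("mask tokens must be 0 or 1 in ", path)
    v == "1"
  }))
  mat
}

#' @rdname read_mask
#' @param mask logical matrix.
#' @param snp_ids,sample_ids optional ids written into the file.
#' @export
write_mask <- function(mask, path, snp_ids = NULL, sample_ids = NULL) {
  stopifnot(is.matrix(mask), is.logical(mask))
  snp_ids <- snp_ids %||% paste0("snp", seq_len(ncol(mask)))
  sample_ids <- sample_ids %||% paste0("s", seq_len(nrow(mask)))
  lines <- c(
    paste(c("#SNP", snp_ids), collapse = "\t"),
    vapply(seq_len(nrow(mask)), function(i) {
      paste(c(sample_ids[i], as.integer(mask[i, ])), collapse = "\t")
    }, character(1L))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Stack panels typed on heterogeneous SNP sets
#'
#' Combines reference and study panels into one large matrix: rows are the
#' concatenated samples, columns the union of SNP ids in first-seen order.
#' SNPs a panel never typed become missing entries in its rows -- the
#' chip-mismatch structure the completion solvers then fill.
#'
#' @param panels list of [genotype_panel()] objects sharing a ploidy.
#' @param rename_duplicates if `TRUE`, duplicate sample ids across panels are
#'   suffixed `.p<k>`; otherwise duplicates are an error.
#' @return A `genotype_panel` with attribute `panel_rows`: a list of row
#'   index ranges, one per input panel, so study rows can be located for
#'   evaluation.
#' @export
stack_panels <- function(panels, rename_duplicates = FALSE) {
  stopifnot(length(panels) >= 1L)
  lapply(panels, function(p) stopifnot(inherits(p, "genotype_panel")))
  ploidies <- unique(vapply(panels, `[[`, character(1L), "ploidy"))
  if (length(ploidies) != 1L) {
    stop_ri("cannot stack panels of mixed ploidy: ", paste(ploidies, collapse = ", "))
  }
  sentinel <- panels[[1L]]$missing_sentinel
  all_snps <- unique(unlist(lapply(panels, `[[`, "snp_ids")))
  sample_ids <- unlist(lapply(panels, `[[`, "sample_ids"))
  if (anyDuplicated(sample_ids)) {
    if (!rename_duplicates) {
      stop_ri("duplicate sample ids across panels; set rename_duplicates = TRUE to suffix them")
    }
    sample_ids <- unlist(lapply(seq_along(panels), function(k) {
      paste0(panels[[k]]$sample_ids, ".p", k)
    }))
  }
  n_total <- sum(vapply(panels, function(p) nrow(p$values), integer(1L)))
  values <- matrix(sentinel, nrow = n_total, ncol = length(all_snps))
  panel_rows <- vector("list", length(panels))
  at <- 0L
  for (k in seq_along(panels)) {
    p <- panels[[k]]
    rows <- at + seq_len(nrow(p$values))
    cols <- match(p$snp_ids, all_snps)
    v <- p$values
    if (p$missing_sentinel != sentinel) v[v == p$missing_sentinel] <- sentinel
    values[rows, cols] <- v
    panel_rows[[k]] <- rows
    at <- at + nrow(p$values)
  }
  out <- genotype_panel(values, ploidies,
    sample_ids = sample_ids, snp_ids = all_snps,
    missing_sentinel = sentinel
  )
  attr(out, "panel_rows") <- panel_rows
  out
}
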