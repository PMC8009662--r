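# File formats: 16-bit TIFF images and masks, CSV tables, JSON sidecars.

TIFF_SCALE <- 65535

#' Write a two-channel image as a multi-page 16-bit TIFF
#'
#' Channels become pages (channel axis first). Intensities in AU are scaled
#' by `scale` into the 16-bit range; values are clipped at the top of the
#' range.
#'
#' @param image Numeric array `c(h, w, 2)`.
#' @param path Output path.
#' @param scale AU value mapped to the 16-bit maximum (default 1000).
#' @return `path`, invisibly.
#' @export
write_image_tiff <- function(image, path, scale = 1000) {
  stopifnot(length(dim(image)) == 3L)
  pages <- lapply(seq_len(dim(image)[3]), function(ch) {
    pmin(pmax(image[, , ch] / scale, 0), 1)
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a multi-page 16-bit TIFF into a two-channel image
#'
#' @param path TIFF path written by [write_image_tiff()].
#' @param scale AU value of the 16-bit maximum (must match the writer).
#' @return Numeric array `c(h, w, n_pages)` in AU.
#' @export
read_image_tiff <- function(path, scale = 1000) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  out <- array(0, dim = c(dim(pages[[1]])[1:2], length(pages)))
  for (ch in seq_along(pages)) {
    pg <- pages[[ch]]
    if (length(dim(pg)) == 3L) pg <- pg[, , 1]
    out[, , ch] <- pg * scale
  }
  out
}

#' Write a label mask as a single-page 16-bit TIFF
#' @param mask Integer matrix (0 = background).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask_tiff <- function(mask, path) {
  stopifnot(is.matrix(mask), all(mask >= 0), all(mask < TIFF_SCALE))
  tiff::writeTIFF(mask / TIFF_SCALE, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a label mask written by [write_mask_tiff()]
#' @param path TIFF path.
#' @return Integer matrix.
#' @export
read_mask_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  matrix(as.integer(round(m * TIFF_SCALE)), nrow(m), ncol(m))
}

#' Write a ground-truth sidecar JSON
#' @param truth Ground-truth list (from the synthetic generators).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Read a ground-truth sidecar JSON
#' @param path JSON path.
#' @return The ground-truth list.
#' @export
read_truth_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

# 6-significant-digit numeric formatting for CSV output.
format_csv_num <- function(df) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(v) signif(v, 6))
  df
}

#' Write a POME table to CSV
#' @param pome POME table data frame (from [measure_polarity()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pome_csv <- function(pome, path) {
  utils::write.csv(format_csv_num(pome), path, row.names = FALSE)
  invisible(path)
}

#' Read a POME table from CSV
#' @param path CSV path.
#' @return POME table data frame.
#' @export
read_pome_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a lineage record to long-format CSV
#'
#' One row per cell per timepoint with columns `cell_id`, `timepoint`,
#' `state`, `polarity_call`, `parent_id`, `division_type`; the division
#' type is written on the parent's final row (the timepoint before its
#' daughters appear), which is sufficient to reconstruct the division
#' table on read.
#'
#' @param record A [lineage_record()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lineage_csv <- function(record, path) {
  stopifnot(inherits(record, "lineage_record"))
  cc <- record$cells
  dv <- record$divisions
  div_col <- rep(NA_character_, nrow(cc))
  if (nrow(dv)) {
    idx <- match(paste(dv$parent_id, dv$timepoint - 1),
                 paste(cc$cell_id, cc$timepoint))
    div_col[idx[!is.na(idx)]] <- dv$type[!is.na(idx)]
  }
  out <- cbind(cc[, c("cell_id", "timepoint", "state", "polarity_call",
                      "parent_id")],
               division_type = div_col)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a lineage record from long-format CSV
#'
#' Rebuilds the division table from parent links: each divided cell's
#' daughters are the cells whose `parent_id` points at it, appearing at
#' the timepoint after the parent's final row.
#'
#' @param path CSV path written by [write_lineage_csv()].
#' @return A [lineage_record()].
#' @export
read_lineage_csv <- function(path) {
  cc <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "timepoint", "state", "polarity_call", "parent_id")
  if (!all(need %in% names(cc))) {
    stop("lineage CSV must have columns ", paste(need, collapse = ", "))
  }
  if (!all(cc$state %in% LINEAGE_STATES)) {
    stop("lineage CSV contains unknown states: ",
         paste(setdiff(unique(cc$state), LINEAGE_STATES), collapse = ", "))
  }
  first_rows <- cc[!duplicated(cc$cell_id), ]
  kids <- first_rows[!is.na(first_rows$parent_id), ]
  if (nrow(kids)) {
    birth <- tapply(cc$timepoint, cc$cell_id, min)
    ord <- kids[order(kids$parent_id, kids$cell_id), ]
    sp <- split(ord$cell_id, ord$parent_id)
    parents <- as.integer(names(sp))
    d1 <- vapply(sp, function(v) as.integer(v[1]), integer(1))
    d2 <- vapply(sp, function(v) if (length(v) >= 2L) as.integer(v[2])
                 else NA_integer_, integer(1))
    dtp <- unname(birth[as.character(d1)])
    # type from the parent's division_type annotation, if present
    type <- rep(NA_character_, length(parents))
    if ("division_type" %in% names(cc)) {
      ann <- cc[!is.na(cc$division_type) & cc$division_type != "", ]
      type <- ann$division_type[match(parents, ann$cell_id)]
    }
    divisions <- data.frame(parent_id = parents, daughter1 = unname(d1),
                            daughter2 = unname(d2), timepoint = dtp,
                            type = type, stringsAsFactors = FALSE)
  } else {
    divisions <- data.frame(parent_id = integer(0), daughter1 = integer(0),
                            daughter2 = integer(0), timepoint = integer(0),
                            type = character(0), stringsAsFactors = FALSE)
  }
  cols <- c("cell_id", "timepoint", "state", "polarity_call", "parent_id")
  lineage_record(cc[, cols], divisions,
                 timepoints = sort(unique(cc$timepoint)))
}

#' Write persistence results to CSV
#' @param results List of [measure_persistence()] results.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_persistence_csv <- function(results, path) {
  df <- do.call(rbind, lapply(results, function(r) {
    data.frame(cell_id = r$cell_id,
               persistence_minutes = r$persistence_minutes,
               censored = r$censored)
  }))
  utils::write.csv(format_csv_num(df), path, row.names = FALSE)
  invisible(path)
}
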