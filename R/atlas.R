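#' Build a toy paired atlas
#'
#' Creates an atlas table of homologous left/right region pairs plus optional
#' unpaired midline regions. The table plays the role of a real parcellation
#' lookup (e.g. the 132-region combination of a cortical/subcortical atlas
#' with a cerebellar atlas): it defines which L/R comparisons exist. The
#' default full-size configuration, `make_toy_atlas(66)`, yields 132 regions.
#'
#' @param n_pairs Number of homologous L/R pairs (must be >= 1).
#' @param n_unpaired Number of unpaired midline regions (hemisphere `"M"`).
#' @return A data frame of class `atlas_table` with columns `roi_id` (integer),
#'   `name` (unique), `hemisphere` (`"L"`, `"R"` or `"M"`), and `pair_id`
#'   (integer, `NA` for midline regions). Paired regions are named
#'   `"<base> L"` / `"<base> R"`.
#' @examples
#' atlas <- make_toy_atlas(4)
#' nrow(atlas)  # 8
#' @export
make_toy_atlas <- function(n_pairs, n_unpaired = 0L) {
  n_pairs <- as.integer(n_pairs)
  n_unpaired <- as.integer(n_unpaired)
  if (is.na(n_pairs) || n_pairs < 1L)
    stop("'n_pairs' must be >= 1: at least one homologous pair is required ",
         "for a laterality analysis")
  if (is.na(n_unpaired) || n_unpaired < 0L)
    stop("'n_unpaired' must be a nonnegative count")

  base <- sprintf("Region %03d", seq_len(n_pairs))
  paired <- data.frame(
    name = as.vector(rbind(paste(base, "L"), paste(base, "R"))),
    hemisphere = rep(c("L", "R"), n_pairs),
    pair_id = rep(seq_len(n_pairs), each = 2L),
    stringsAsFactors = FALSE
  )
  if (n_unpaired > 0L) {
    mid <- data.frame(
      name = sprintf("Midline %03d M", seq_len(n_unpaired)),
      hemisphere = rep("M", n_unpaired),
      pair_id = NA_integer_,
      stringsAsFactors = FALSE
    )
    paired <- rbind(paired, mid)
  }
  atlas <- data.frame(roi_id = seq_len(nrow(paired)), paired,
                      stringsAsFactors = FALSE)
  class(atlas) <- c("atlas_table", "data.frame")
  atlas
}

#' Validate an atlas table
#'
#' Checks the structural invariants an atlas must satisfy before any
#' laterality computation: unique names, hemispheres in {L, R, M}, and each
#' `pair_id` mapping to exactly one left and one right region.
#'
#' @param atlas A data frame with columns `roi_id`, `name`, `hemisphere`,
#'   `pair_id`.
#' @return The validated atlas, invisibly, with class `atlas_table`.
#' @export
validate_atlas <- function(atlas) {
  req <- c("roi_id", "name", "hemisphere", "pair_id")
  miss <- setdiff(req, names(atlas))
  if (length(miss))
    stop("atlas is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(atlas$name))
    stop("atlas region names must be unique")
  if (anyDuplicated(atlas$roi_id))
    stop("atlas roi_id values must be unique")
  if (!all(atlas$hemisphere %in% c("L", "R", "M")))
    stop("hemisphere labels must be 'L', 'R' or 'M'")
  if (any(is.na(atlas$pair_id) & atlas$hemisphere != "M"))
    stop("paired (L/R) regions must carry a pair_id")
  if (any(!is.na(atlas$pair_id) & atlas$hemisphere == "M"))
    stop("midline regions must have a null pair_id")
  pairs <- unique(atlas$pair_id[!is.na(atlas$pair_id)])
  for (p in pairs) {
    hemi <- sort(atlas$hemisphere[!is.na(atlas$pair_id) & atlas$pair_id == p])
    if (!identical(hemi, c("L", "R")))
      stop("pair_id ", p, " must map to exactly one L and one R region")
  }
  if (!inherits(atlas, "atlas_table"))
    class(atlas) <- c("atlas_table", class(atlas))
  invisible(atlas)
}

#' Homologous pairs of an atlas
#'
#' @param atlas An `atlas_table`.
#' @return A data frame with one row per pair: `pair_id`, `roi_left`,
#'   `roi_right` (roi_ids), `name_left`, `name_right`.
#' @export
atlas_pairs <- function(atlas) {
  validate_atlas(atlas)
  p <- atlas[!is.na(atlas$pair_id), , drop = FALSE]
  left <- p[p$hemisphere == "L", c("pair_id", "roi_id", "name")]
  right <- p[p$hemisphere == "R", c("pair_id", "roi_id", "name")]
  names(left) <- c("pair_id", "roi_left", "name_left")
  names(right) <- c("pair_id", "roi_right", "name_right")
  out <- merge(left, right, by = "pair_id", sort = TRUE)
  out[order(out$pair_id), c("pair_id", "roi_left", "roi_right",
                            "name_left", "name_right")]
}

#' Read / write an atlas table as TSV
#'
#' The on-disk format is a four-column tab-separated file with header
#' `roi_id`, `name`, `hemisphere`, `pair_id` (empty for midline regions).
#'
#' @param atlas An `atlas_table`.
#' @param path File path.
#' @return `read_atlas` returns a validated `atlas_table`;
#'   `write_atlas` returns `path` invisibly.
#' @export
write_atlas <- function(atlas, path) {
  validate_atlas(atlas)
  utils::write.table(atlas, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_atlas
#' @export
read_atlas <- function(path) {
  atlas <- utils::read.delim(path, stringsAsFactors = FALSE,
                             na.strings = c("NA", ""))
  atlas$pair_id <- as.integer(atlas$pair_id)
  atlas$roi_id <- as.integer(atlas$roi_id)
  class(atlas) <- c("atlas_table", "data.frame")
  validate_atlas(atlas)
  atlas
}
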