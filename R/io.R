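#' Read a statistic matrix from delimited text
#'
#' Accepts whitespace- or comma-delimited square numeric text.  The parser is
#' strict: ragged rows, non-numeric tokens and asymmetric cells are rejected
#' with the offending row/column named.
#'
#' @param path File path.
#' @param tol Symmetry tolerance passed to [stat_matrix()].
#' @return A [stat_matrix()].
#' @export
read_stat_matrix <- function(path, tol = 1e-8) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  toks <- lapply(lines, function(l) strsplit(trimws(l), "[,[:space:]]+")[[1]])
  len <- lengths(toks)
  if (length(unique(len)) != 1L)
    abort(sprintf("ragged rows: row %d has %d fields, row 1 has %d",
                  which(len != len[1])[1], len[len != len[1]][1], len[1]),
          class = "ictfce_parse_error")
  vals <- suppressWarnings(lapply(toks, as.numeric))
  for (i in seq_along(vals)) {
    bad <- which(is.na(vals[[i]]) & toks[[i]] != "NA")
    if (length(bad))
      abort(sprintf("non-numeric token '%s' at row %d, column %d",
                    toks[[i]][bad[1]], i, bad[1]),
            class = "ictfce_parse_error")
  }
  m <- do.call(rbind, vals)
  stat_matrix(m, tol = tol)
}

#' Write a matrix as full-precision delimited text
#'
#' Values are written with 17 significant digits so a write/read round trip
#' is lossless for doubles, keeping cross-process oracle comparisons exact.
#'
#' @param m Matrix (a [stat_matrix()], `tfce_map` or plain matrix).
#' @param path Output path.
#' @export
write_stat_matrix <- function(m, path) {
  txt <- apply(unclass(m), 1L, function(r)
    paste(formatC(r, format = "g", digits = 17), collapse = "\t"))
  writeLines(txt, path)
  invisible(path)
}

#' Plain-text 3D volume format
#'
#' A dependency-free fixture format: the first line holds the three
#' dimensions, subsequent whitespace-separated values fill the array in
#' column-major (R native) order.  An optional second header token `mask`
#' marks a 0/1 mask volume.
#'
#' @param path File path.
#' @return `read_voxel_text()`: a 3D array.
#' @export
read_voxel_text <- function(path) {
  lines <- readLines(path)
  dims <- as.integer(strsplit(trimws(lines[1]), "[[:space:]]+")[[1]])
  if (length(dims) != 3L || any(is.na(dims)))
    abort("first line must give three dimensions", class = "ictfce_parse_error")
  toks <- unlist(strsplit(trimws(lines[-1]), "[[:space:]]+"))
  vals <- as.numeric(toks[nzchar(toks)])
  if (length(vals) != prod(dims))
    abort(sprintf("expected %d values, found %d", prod(dims), length(vals)),
          class = "ictfce_parse_error")
  array(vals, dims)
}

#' @rdname read_voxel_text
#' @param x 3D array to write.
#' @export
write_voxel_text <- function(x, path) {
  stopifnot(length(dim(x)) == 3L)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(dim(x), collapse = " "), con)
  writeLines(paste(formatC(as.numeric(x), format = "g", digits = 17),
                   collapse = " "), con)
  invisible(path)
}

#' NIfTI input/output for voxel TFCE
#'
#' Thin wrappers over \pkg{RNifti}.  The input affine/header is carried
#' through untouched to the output TFCE map; no world-coordinate reasoning
#' happens anywhere in the package (adjacency is array-index based).
#'
#' @param path Statistic volume path.
#' @param mask_path Optional mask volume (non-zero = in mask).
#' @param connectivity Adjacency rule, see [voxel_image()].
#' @return `read_voxel_nifti()`: a [voxel_image()] with the source image
#'   stored in attribute `template`.
#' @export
read_voxel_nifti <- function(path, mask_path = NULL, connectivity = 26) {
  nii <- RNifti::readNifti(path)
  stats <- array(as.numeric(nii), dim(nii)[1:3])
  mask <- if (!is.null(mask_path)) {
    m <- RNifti::readNifti(mask_path)
    array(as.numeric(m) != 0, dim(m)[1:3])
  } else NULL
  img <- voxel_image(stats, mask = mask, connectivity = connectivity)
  attr(img, "template") <- nii
  img
}

#' @rdname read_voxel_nifti
#' @param x 3D array of TFCE values.
#' @param template A `niftiImage` whose header/affine is reused.
#' @export
write_voxel_nifti <- function(x, path, template = NULL) {
  img <- if (!is.null(template))
    RNifti::asNifti(array(x, dim(x)), reference = template)
  else RNifti::asNifti(array(x, dim(x)))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a two-column design file
#'
#' Whitespace-delimited `subject_id group_label` lines; subject ids must
#' match the matrix file names (with or without extension) in the data
#' directory.
#'
#' @param path Design file path.
#' @return Tibble with `subject`, `group`.
#' @export
read_design <- function(path) {
  d <- utils::read.table(path, header = FALSE, col.names = c("subject", "group"),
                         colClasses = c("character", "character"))
  as_tibble(d)
}

#' Read a node-to-network partition file
#'
#' Whitespace-delimited `node_index network_name` lines.
#'
#' @param path Partition file path.
#' @param n_rois Expected number of ROIs (checked when given).
#' @return Character vector of network names indexed by node.
#' @export
read_network_partition <- function(path, n_rois = NULL) {
  d <- utils::read.table(path, header = FALSE, col.names = c("node", "network"),
                         colClasses = c("integer", "character"))
  out <- character(max(d$node))
  out[d$node] <- d$network
  if (!is.null(n_rois) && length(out) != n_rois)
    abort("partition does not cover every node", class = "ictfce_parse_error")
  out
}

# machine-readable provenance sidecar next to an output file
write_provenance <- function(output_path, record) {
  record$package <- "ictfce"
  record$version <- as.character(utils::packageVersion("ictfce"))
  record$r_version <- R.version.string
  path <- paste0(output_path, ".provenance.json")
  jsonlite::write_json(record, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
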