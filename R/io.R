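# Delimited-text I/O and the bundled Destrieux 148-ROI lookup.

#' Destrieux 148-ROI names
#'
#' The 74 sulco-gyral labels of the Destrieux parcellation, prefixed
#' `lh_`/`rh_`, left hemisphere first.
#'
#' @return Character vector of length 148.
#' @export
destrieux_rois <- function() {
  destrieux_table()$roi
}

#' Destrieux ROI-to-lobe lookup
#'
#' A conventional assignment of each Destrieux region to one of six lobes
#' (frontal, parietal, temporal, occipital, insula, limbic), used for
#' module composition reports.
#'
#' @return Named character vector: lobe keyed by ROI name.
#' @export
destrieux_lobes <- function() {
  tab <- destrieux_table()
  setNames(tab$lobe, tab$roi)
}

destrieux_table <- function() {
  path <- system.file("extdata", "destrieux_148.tsv", package = "scnet",
                      mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}

#' Read / write a morphometry table
#'
#' Tab-delimited, header row of ROI names after the `subject_id`, `group`,
#' `age`, `sex` columns. Values are written with full double precision so
#' tables round-trip losslessly.
#'
#' @param path File path.
#' @return `read_morphometry`: the data.frame.
#' @export
read_morphometry <- function(path) {
  read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' @rdname read_morphometry
#' @param x Data.frame to write.
#' @export
write_morphometry <- function(x, path) {
  write_tsv_full(x, path)
}

#' Read / write a cognitive score table
#' @param path File path.
#' @return `read_cognitive`: the data.frame.
#' @export
read_cognitive <- function(path) {
  read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' @rdname read_cognitive
#' @param x Data.frame to write.
#' @export
write_cognitive <- function(x, path) {
  write_tsv_full(x, path)
}

# full-precision writer shared by all table outputs (deterministic bytes)
write_tsv_full <- function(x, path) {
  num <- vapply(x, is.double, logical(1))
  x[num] <- lapply(x[num], function(col) sprintf("%.17g", col))
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a numeric matrix with row/column names as delimited text
#' @param m Matrix.
#' @param path File path.
#' @export
write_matrix <- function(m, path) {
  df <- data.frame(name = rownames(m) %||% seq_len(nrow(m)), m,
                   check.names = FALSE)
  write_tsv_full(df, path)
}

#' @rdname write_matrix
#' @return `read_matrix`: the matrix with dimnames restored.
#' @export
read_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Deterministic spherical node layout (synthetic coordinates)
#'
#' Placeholder BrainNet coordinates when no ROI centroid file is supplied:
#' points on a Fibonacci sphere of the given radius, left-hemisphere ROIs
#' (first half) mirrored to x < 0. Purely synthetic — for visualization
#' layout only, not anatomy.
#'
#' @param n Number of nodes.
#' @param radius Sphere radius in mm.
#' @return n x 3 matrix of x, y, z.
#' @export
sphere_layout <- function(n, radius = 70) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  xyz <- radius * cbind(x = cos(theta) * sin(phi),
                        y = sin(theta) * sin(phi),
                        z = cos(phi))
  half <- seq_len(ceiling(n / 2))
  xyz[half, 1] <- -abs(xyz[half, 1])
  xyz[-half, 1] <- abs(xyz[-half, 1])
  round(xyz, 3)
}

#' Export a BrainNet-Viewer node (and optional edge) file
#'
#' Standard BrainNet `.node` text format: six whitespace-separated columns
#' `x y z color size label`, one row per ROI, with module membership as the
#' color column and degree as the size column. Optionally writes the
#' adjacency as a whitespace-delimited square matrix (`.edge`).
#'
#' @param partition Named integer vector: module id per ROI.
#' @param degrees Named numeric vector: node degree per ROI (same ROIs).
#' @param coordinates n x 3 matrix of coordinates with rownames matching
#'   the ROI names, or NULL for the deterministic [sphere_layout()].
#' @param path Output path for the `.node` file.
#' @param adjacency Optional adjacency matrix for a companion `.edge` file.
#' @return Invisibly, the `.node` path.
#' @export
export_brainnet <- function(partition, degrees, coordinates = NULL,
                            path, adjacency = NULL) {
  rois <- names(partition)
  if (is.null(rois)) stop("partition must be named by ROI")
  if (!setequal(rois, names(degrees)))
    stop("partition and degrees name different ROIs")
  degrees <- degrees[rois]
  if (is.null(coordinates)) {
    coordinates <- sphere_layout(length(rois))
    rownames(coordinates) <- rois
  }
  missing <- setdiff(rois, rownames(coordinates))
  if (length(missing))
    stop("no coordinates for ROI(s): ", paste(missing, collapse = ", "))
  coordinates <- coordinates[rois, , drop = FALSE]
  lines <- sprintf("%g\t%g\t%g\t%d\t%g\t%s",
                   coordinates[, 1], coordinates[, 2], coordinates[, 3],
                   as.integer(partition), degrees, rois)
  writeLines(lines, path)
  if (!is.null(adjacency)) {
    edge_path <- sub("\\.node$", ".edge", path)
    if (identical(edge_path, path)) edge_path <- paste0(path, ".edge")
    write.table(adjacency, edge_path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Parse a BrainNet node file back into partition and degrees
#' @param path `.node` file path.
#' @return List: `partition`, `degrees`, `coordinates` (all named/rowed by
#'   the label column).
#' @export
read_brainnet_node <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("x", "y", "z", "color", "size", "label")
  list(partition = setNames(as.integer(df$color), df$label),
       degrees = setNames(df$size, df$label),
       coordinates = structure(as.matrix(df[, 1:3]),
                               dimnames = list(df$label, c("x", "y", "z"))))
}
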