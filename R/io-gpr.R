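#' Two-color array containers
#'
#' A \code{TwoColorArray} holds per-spot foreground/background intensities for
#' the two scanner channels, spot coordinates (block, row, column), GenePix
#' quality flags (negative = bad) and the dye orientation of the hybridization.
#' Channel 1 is the 635 nm (red/Cy5) channel, channel 2 the 532 nm
#' (green/Cy3) channel.
#'
#' @param spots data frame with columns \code{spot_id}, \code{probe_id},
#'   \code{block}, \code{row}, \code{column}, \code{fg_ch1}, \code{bg_ch1},
#'   \code{fg_ch2}, \code{bg_ch2}, \code{flag}.
#' @param dye_orientation \code{"treatment_in_ch1"} or
#'   \code{"treatment_in_ch2"}: which channel carries the treatment sample.
#' @param array_id identifier for the slide.
#' @return An object of class \code{TwoColorArray}.
#' @export
two_color_array <- function(spots, dye_orientation = c("treatment_in_ch1", "treatment_in_ch2"),
                            array_id = "array1") {
  dye_orientation <- match.arg(dye_orientation)
  need <- c("spot_id", "probe_id", "block", "row", "column",
            "fg_ch1", "bg_ch1", "fg_ch2", "bg_ch2", "flag")
  miss <- setdiff(need, names(spots))
  if (length(miss)) stop("spots table lacks column(s): ", paste(miss, collapse = ", "))
  spots <- as.data.frame(spots)[need]
  ints <- c("fg_ch1", "bg_ch1", "fg_ch2", "bg_ch2")
  if (any(as.matrix(spots[ints]) < 0)) stop("negative intensities")
  key <- paste(spots$block, spots$row, spots$column)
  if (anyDuplicated(key)) stop("duplicate (block, row, column) spot coordinates")
  structure(list(spots = spots, dye_orientation = dye_orientation,
                 array_id = as.character(array_id),
                 channel_map = c(ch1 = "635", ch2 = "532")),
            class = "TwoColorArray")
}

#' Read a GenePix GPR result file
#'
#' Accepts the GPR dialect: an optional ATF header block (first line "ATF",
#' second line two counts, then \code{n} header records), followed by a
#' tab-separated table. Any column superset is accepted; the nine columns
#' Block, Row, Column, ID, F635 Median, B635 Median, F532 Median, B532 Median
#' and Flags are required (median statistics, the GenePix-era convention).
#' The 635 nm channel maps to channel 1 and 532 nm to channel 2.
#'
#' @param path path to the GPR file.
#' @param dye_orientation dye orientation of this hybridization (not stored in
#'   GPR files; comes from the experiment's targets table).
#' @param array_id identifier; defaults to the file name.
#' @return A \code{\link{two_color_array}}.
#' @export
read_gpr <- function(path, dye_orientation = "treatment_in_ch1",
                     array_id = tools::file_path_sans_ext(basename(path))) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  start <- 1L
  if (length(lines) >= 2L && grepl("^ATF", lines[1])) {
    counts <- strsplit(lines[2], "\t")[[1]]
    n_hdr <- suppressWarnings(as.integer(counts[1]))
    if (is.na(n_hdr)) stop("malformed ATF header count line")
    start <- 3L + n_hdr
  }
  if (start > length(lines)) stop("no data table after ATF header block")
  tab <- utils::read.delim(text = paste(lines[start:length(lines)], collapse = "\n"),
                           check.names = FALSE, quote = "\"",
                           stringsAsFactors = FALSE)
  need <- c("Block", "Row", "Column", "ID", "F635 Median", "B635 Median",
            "F532 Median", "B532 Median", "Flags")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("GPR file lacks required column(s): ",
                         paste(miss, collapse = ", "))
  spots <- data.frame(
    spot_id = sprintf("%d.%d.%d", tab$Block, tab$Row, tab$Column),
    probe_id = as.character(tab$ID),
    block = as.integer(tab$Block), row = as.integer(tab$Row),
    column = as.integer(tab$Column),
    fg_ch1 = as.numeric(tab$`F635 Median`), bg_ch1 = as.numeric(tab$`B635 Median`),
    fg_ch2 = as.numeric(tab$`F532 Median`), bg_ch2 = as.numeric(tab$`B532 Median`),
    flag = as.integer(tab$Flags), stringsAsFactors = FALSE)
  two_color_array(spots, dye_orientation, array_id)
}

#' Write a TwoColorArray as a GPR-style file
#'
#' Emits a minimal ATF header and the nine-column table that
#' \code{\link{read_gpr}} requires, so synthetic arrays round-trip.
#'
#' @param array a \code{\link{two_color_array}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_gpr <- function(array, path) {
  stopifnot(inherits(array, "TwoColorArray"))
  s <- array$spots
  hdr <- c("ATF\t1.0", "2\t9",
           sprintf("\"Type=GenePix Results 3\""),
           sprintf("\"ArrayId=%s\"", array$array_id))
  tab <- data.frame(Block = s$block, Row = s$row, Column = s$column,
                    ID = s$probe_id,
                    `F635 Median` = s$fg_ch1, `B635 Median` = s$bg_ch1,
                    `F532 Median` = s$fg_ch2, `B532 Median` = s$bg_ch2,
                    Flags = s$flag, check.names = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.TwoColorArray <- function(x, ...) {
  cat("TwoColorArray", x$array_id, "with", nrow(x$spots), "spots;",
      x$dye_orientation, "\n")
  invisible(x)
}
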