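# Constant flanks used in simulated amplicons. Arbitrary stop-free anchors;
# extraction is positional, so their exact sequence never matters downstream.
.FLANK5 <- "ACTTCCGG"
.SPACER <- "CGCCAGTG"
.FLANK3 <- "GTTCTAGA"

#' Define an amplicon read layout
#'
#' A read layout is an ordered set of fixed-width segments. Constant
#' segments are given as literal sequences; variable segments (insert,
#' barcode, umi) as integer widths. Segment offsets are derived from the
#' order given.
#'
#' @param ... Named segments in read order: either a literal DNA string
#'   (constant segment) or a single integer width (variable segment).
#' @return A `read_layout` tibble with columns `segment`, `width`,
#'   `fixed_seq`, `start`, `end`.
#' @export
#' @examples
#' read_layout(flank5 = "ACTT", barcode = 24L, flank3 = "GT")
read_layout <- function(...) {
  segs <- list(...)
  stopifnot(length(segs) > 0, !is.null(names(segs)), all(names(segs) != ""))
  width <- vapply(segs, function(s) {
    if (is.character(s)) nchar(s) else as.integer(s)
  }, integer(1))
  fixed <- vapply(segs, function(s) {
    if (is.character(s)) s else NA_character_
  }, character(1))
  stopifnot(all(width > 0))
  out <- tibble::tibble(
    segment   = names(segs),
    width     = width,
    fixed_seq = unname(fixed),
    end       = cumsum(width)
  )
  out$start <- out$end - out$width + 1L
  out <- out[, c("segment", "width", "fixed_seq", "start", "end")]
  class(out) <- c("read_layout", class(out))
  out
}

#' Default read layouts per sample type
#'
#' Linkage reads carry the 48-nt insert and the 24-nt barcode; gDNA/cDNA
#' barcode reads carry only the barcode; deep-mutational-scanning reads
#' carry a 7-nt UMI and the insert. `umi = TRUE` prepends a 7-nt UMI to the
#' barcode layouts.
#'
#' @param type One of `"linkage"`, `"gdna"`, `"mrna"`, `"dms_gdna"`,
#'   `"dms_mrna"`.
#' @param umi Include a leading 7-nt UMI in barcode-counting layouts.
#' @return A `read_layout`.
#' @export
default_layout <- function(type = c("linkage", "gdna", "mrna",
                                    "dms_gdna", "dms_mrna"),
                           umi = FALSE) {
  type <- match.arg(type)
  if (type == "linkage") {
    return(read_layout(flank5 = .FLANK5, insert = 48L, spacer = .SPACER,
                       barcode = 24L, flank3 = .FLANK3))
  }
  if (type %in% c("dms_gdna", "dms_mrna")) {
    return(read_layout(umi = 7L, flank5 = .FLANK5, insert = 48L))
  }
  if (umi) {
    read_layout(umi = 7L, flank5 = .FLANK5, barcode = 24L, flank3 = .FLANK3)
  } else {
    read_layout(flank5 = .FLANK5, barcode = 24L, flank3 = .FLANK3)
  }
}

layout_width <- function(layout) sum(layout$width)

layout_has <- function(layout, segment) segment %in% layout$segment

# Extract a named variable segment from a character vector of reads.
# Reads shorter than the layout must be removed by the caller first.
layout_extract <- function(reads, layout, segment) {
  row <- layout[layout$segment == segment, ]
  if (nrow(row) != 1L) stop("layout has no segment '", segment, "'")
  substr(reads, row$start, row$end)
}
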