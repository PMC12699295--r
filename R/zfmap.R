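#' Zinc-finger window map for CTCF motifs
#'
#' CTCF contacts its motif through 11 zinc fingers (ZFs), each engaging
#' roughly a 3-bp triplet.  This map assigns every ZF a closed, inclusive
#' window of motif-relative coordinates, with the convention that 0 is the
#' motif center, negative coordinates lie on the N-terminal-protein side, and
#' ZF11..ZF1 tile the motif from negative to positive.  Two flanking
#' nucleosome-depleted-region (NDR) windows serve as the accessibility
#' reference.
#'
#' @param zf_width window width per ZF in bp (default 3).
#' @param ndr_n,ndr_c length-2 integer vectors giving the N- and C-terminal
#'   NDR windows in motif-relative bp.
#' @return A data.frame with columns `region`, `start`, `end`, `type`
#'   (`"zf"` or `"ndr"`) and, for ZF rows, `cluster` (`"ZF1-2"`, `"ZF3-8"`,
#'   `"ZF9-11"`).
#' @examples
#' zf_map()
#' @export
zf_map <- function(zf_width = 3L, ndr_n = c(-60L, -20L), ndr_c = c(20L, 60L)) {
  stopifnot(zf_width >= 1L, length(ndr_n) == 2L, length(ndr_c) == 2L)
  n_zf <- 11L
  span <- n_zf * zf_width
  starts <- seq.int(-(span %/% 2L), by = zf_width, length.out = n_zf)
  # ZF11 sits at the most negative (N-terminal-side) window, ZF1 at the most
  # positive one.
  zf_id <- paste0("ZF", n_zf:1L)
  zf <- data.frame(
    region = zf_id,
    start = starts,
    end = starts + zf_width - 1L,
    type = "zf",
    stringsAsFactors = FALSE
  )
  num <- as.integer(sub("ZF", "", zf$region))
  zf$cluster <- ifelse(num <= 2L, "ZF1-2", ifelse(num <= 8L, "ZF3-8", "ZF9-11"))
  ndr <- data.frame(
    region = c("NDR_N", "NDR_C"),
    start = c(ndr_n[1], ndr_c[1]),
    end = c(ndr_n[2], ndr_c[2]),
    type = "ndr",
    cluster = NA_character_,
    stringsAsFactors = FALSE
  )
  map <- rbind(zf, ndr)
  validate_zf_map(map)
  map
}

validate_zf_map <- function(map) {
  zf <- map[map$type == "zf", ]
  zf <- zf[order(zf$start), ]
  if (any(zf$end < zf$start)) stop("ZF windows must have start <= end")
  if (nrow(zf) > 1 && any(zf$start[-1] <= zf$end[-nrow(zf)]))
    stop("ZF windows must be non-overlapping and ordered")
  ndr <- map[map$type == "ndr", ]
  for (i in seq_len(nrow(ndr))) {
    if (any(pmax(zf$start, ndr$start[i]) <= pmin(zf$end, ndr$end[i])))
      stop("NDR windows must be disjoint from ZF windows")
  }
  invisible(map)
}

#' Assign motif-relative positions to ZF / NDR regions
#'
#' @param pos integer vector of motif-relative positions (bp).
#' @param map a ZF map from [zf_map()].
#' @return character vector of region names (`NA` for positions in no window).
#' @export
zf_region_of <- function(pos, map = zf_map()) {
  out <- rep(NA_character_, length(pos))
  for (i in seq_len(nrow(map))) {
    hit <- pos >= map$start[i] & pos <= map$end[i]
    out[hit] <- map$region[i]
  }
  out
}

#' @keywords internal
zf_numbers <- function() paste0("ZF", 1:11)
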