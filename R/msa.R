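## Whole-genome multiple-alignment blocks, represented compactly as
## per-genome ungapped segments. All alignment and genome coordinates are
## 0-based; block ranges are half-open. The segment representation carries
## the full gap structure (a column is a gap for a genome wherever no
## segment covers it), which is all that coordinate projection and
## informative-site computation need.

#' Construct an alignment block set
#'
#' @param blocks data.frame with columns `block_id`, `msa_start`,
#'   `msa_end` (0-based, half-open, in a shared alignment coordinate
#'   system).
#' @param segments data.frame with columns `block_id`, `genome`,
#'   `msa_start`, `length`, `genome_start`: each row is a gap-free aligned
#'   run of `length` bases of `genome` starting at alignment column
#'   `msa_start` and genome position `genome_start`.
#' @param genomes Character vector of all genome names in the alignment.
#' @return An object of class `msa_blocks`.
#' @export
msa_blocks <- function(blocks, segments, genomes) {
  stopifnot(all(c("block_id", "msa_start", "msa_end") %in% names(blocks)),
            all(c("block_id", "genome", "msa_start", "length",
                  "genome_start") %in% names(segments)))
  obj <- list(blocks = blocks, segments = segments, genomes = genomes)
  class(obj) <- "msa_blocks"
  obj
}

#' @export
print.msa_blocks <- function(x, ...) {
  cat("msa_blocks:", nrow(x$blocks), "blocks,", length(x$genomes),
      "genomes,", nrow(x$segments), "segments\n")
  invisible(x)
}

# Intervals (matrix with columns start, end; 0-based half-open) of columns
# covered by every genome within one block.
informative_intervals <- function(blockset, block_id) {
  seg <- blockset$segments[blockset$segments$block_id == block_id, ]
  gs <- unique(seg$genome)
  if (!setequal(gs, blockset$genomes)) {
    return(matrix(numeric(0), ncol = 2))
  }
  starts <- seg$msa_start
  ends <- seg$msa_start + seg$length
  bnd <- sort(unique(c(starts, ends)))
  if (length(bnd) < 2) return(matrix(numeric(0), ncol = 2))
  lo <- bnd[-length(bnd)]
  hi <- bnd[-1]
  n_cov <- vapply(seq_along(lo), function(i) {
    covering <- starts <= lo[i] & ends >= hi[i]
    length(unique(seg$genome[covering]))
  }, 0L)
  keep <- n_cov == length(blockset$genomes)
  cbind(lo[keep], hi[keep])
}

informative_in_window <- function(intervals, w0, w1) {
  if (nrow(intervals) == 0) return(0)
  ov <- pmin(intervals[, 2], w1) - pmax(intervals[, 1], w0)
  sum(pmax(ov, 0))
}

#' Filter alignment blocks by genome presence and informative-site content
#'
#' Blocks missing any genome are dropped. Each retained block is scanned in
#' non-overlapping windows of `window_bp` alignment columns from both ends,
#' trimming end windows until a window has at least `informative_frac`
#' informative sites (sites covered by every genome). A block shorter than
#' one window is evaluated as a single window.
#'
#' @param blockset An [msa_blocks()] object.
#' @param window_bp Window width in alignment columns.
#' @param informative_frac Minimum informative-site fraction per window.
#' @return A filtered (and possibly trimmed) `msa_blocks` object.
#' @export
filter_msa_blocks <- function(blockset, window_bp = 10000,
                              informative_frac = 0.80) {
  stopifnot(inherits(blockset, "msa_blocks"))
  keep_blocks <- list(); keep_segs <- list()
  for (i in seq_len(nrow(blockset$blocks))) {
    b <- blockset$blocks[i, ]
    seg <- blockset$segments[blockset$segments$block_id == b$block_id, ]
    if (!setequal(unique(seg$genome), blockset$genomes)) next
    intervals <- informative_intervals(blockset, b$block_id)
    win_starts <- seq(b$msa_start, b$msa_end - 1, by = window_bp)
    win_ends <- pmin(win_starts + window_bp, b$msa_end)
    ok <- vapply(seq_along(win_starts), function(w) {
      frac <- informative_in_window(intervals, win_starts[w], win_ends[w]) /
        (win_ends[w] - win_starts[w])
      frac >= informative_frac
    }, TRUE)
    if (!any(ok)) next
    lo <- which(ok)[1]
    hi <- utils::tail(which(ok), 1)
    new_start <- win_starts[lo]
    new_end <- win_ends[hi]
    b$msa_start <- new_start
    b$msa_end <- new_end
    # clip segments to the retained column range
    s0 <- pmax(seg$msa_start, new_start)
    s1 <- pmin(seg$msa_start + seg$length, new_end)
    sel <- s1 > s0
    seg <- seg[sel, ]
    shift <- s0[sel] - seg$msa_start
    seg$genome_start <- seg$genome_start + shift
    seg$msa_start <- s0[sel]
    seg$length <- s1[sel] - s0[sel]
    keep_blocks[[length(keep_blocks) + 1L]] <- b
    keep_segs[[length(keep_segs) + 1L]] <- seg
  }
  if (length(keep_blocks) == 0L) {
    return(msa_blocks(blockset$blocks[0, ], blockset$segments[0, ],
                      blockset$genomes))
  }
  msa_blocks(do.call(rbind, keep_blocks), do.call(rbind, keep_segs),
             blockset$genomes)
}

#' Project genome annotations into alignment coordinates
#'
#' Maps each annotation's genomic interval through the gap structure of the
#' retained alignment blocks. Annotations overlapping no retained block are
#' flagged unprojectable; annotations spanning several blocks are projected
#' piecewise and the longest piece is kept, flagged `split`.
#'
#' @param annotations data.frame with at least `element_id`, `genome`,
#'   `start`, `end` (0-based half-open genome coordinates); extra columns
#'   (`strand`, `family`, `element_type`) are carried through.
#' @param blockset An [msa_blocks()] object (typically filtered).
#' @return data.frame with `element_id`, `genome`, carried columns,
#'   `msa_start`, `msa_end`, `block_id`, `projectable`, `split`.
#' @export
project_annotations <- function(annotations, blockset) {
  stopifnot(inherits(blockset, "msa_blocks"))
  carry <- intersect(c("strand", "family", "element_type"),
                     names(annotations))
  out <- annotations[, c("element_id", "genome", carry)]
  out$msa_start <- NA_real_
  out$msa_end <- NA_real_
  out$block_id <- NA_integer_
  out$projectable <- FALSE
  out$split <- FALSE
  seg_all <- blockset$segments
  for (i in seq_len(nrow(annotations))) {
    a <- annotations[i, ]
    seg <- seg_all[seg_all$genome == a$genome, ]
    g0 <- seg$genome_start
    g1 <- seg$genome_start + seg$length
    ov <- pmin(g1, a$end) - pmax(g0, a$start)
    hit <- which(ov > 0)
    if (length(hit) == 0L) next
    pieces <- data.frame(
      block_id = seg$block_id[hit],
      glen = ov[hit],
      msa_lo = seg$msa_start[hit] + pmax(a$start - g0[hit], 0),
      msa_hi = seg$msa_start[hit] + pmin(a$end, g1[hit]) - g0[hit])
    by_block <- split(pieces, pieces$block_id)
    spans <- vapply(by_block, function(p) sum(p$glen), 0)
    best <- by_block[[which.max(spans)]]
    out$msa_start[i] <- min(best$msa_lo)
    out$msa_end[i] <- max(best$msa_hi)
    out$block_id[i] <- best$block_id[1]
    out$projectable[i] <- TRUE
    out$split[i] <- length(by_block) > 1L || sum(pieces$glen) < a$end - a$start
  }
  out
}

#' Write alignment blocks as MAF text
#'
#' @param blockset An [msa_blocks()] object.
#' @param genomes Named character vector of genome sequences.
#' @param file Output path.
#' @param contig Contig name used in `s` lines.
#' @return `file`, invisibly.
#' @export
write_maf <- function(blockset, genomes, file, contig = "chr1") {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("##maf version=1", con)
  for (i in seq_len(nrow(blockset$blocks))) {
    b <- blockset$blocks[i, ]
    width <- b$msa_end - b$msa_start
    writeLines("a score=0", con)
    for (g in blockset$genomes) {
      seg <- blockset$segments[blockset$segments$block_id == b$block_id &
                                 blockset$segments$genome == g, ]
      if (nrow(seg) == 0L) next
      seg <- seg[order(seg$msa_start), ]
      buf <- rep(charToRaw("-"), width)
      graw <- charToRaw(genomes[[g]])
      for (k in seq_len(nrow(seg))) {
        cols <- (seg$msa_start[k] - b$msa_start) + seq_len(seg$length[k])
        buf[cols] <- graw[seg$genome_start[k] + seq_len(seg$length[k])]
      }
      writeLines(sprintf("s %s.%s %d %d + %d %s", g, contig,
                         min(seg$genome_start), sum(seg$length),
                         nchar(genomes[[g]]), rawToChar(buf)), con)
    }
    writeLines("", con)
  }
  invisible(file)
}

#' Read MAF text into an alignment block set
#'
#' Blocks are assigned consecutive non-overlapping ranges in a fresh
#' alignment coordinate system (MAF itself has no global column system);
#' within-block gap structure is reconstructed exactly.
#'
#' @param file MAF path.
#' @return An [msa_blocks()] object.
#' @export
read_maf <- function(file) {
  lines <- readLines(file)
  blocks <- list(); segs <- list()
  offset <- 0; bid <- 0L; width <- 0L
  genomes <- character(0)
  flush_block <- function() {
    if (bid > 0L && width > 0L) {
      blocks[[bid]] <<- data.frame(block_id = bid, msa_start = offset,
                                   msa_end = offset + width)
      offset <<- offset + width
    }
  }
  for (ln in lines) {
    if (startsWith(ln, "a")) {
      flush_block()
      bid <- bid + 1L
      width <- 0L
    } else if (startsWith(ln, "s ")) {
      f <- strsplit(trimws(ln), "\\s+")[[1]]
      src <- sub("\\..*$", "", f[2])
      genomes <- union(genomes, src)
      gstart <- as.integer(f[3])
      text <- f[7]
      width <- max(width, nchar(text))
      ch <- charToRaw(text)
      isbase <- ch != charToRaw("-")
      r <- rle(as.vector(isbase))
      pos <- c(0L, cumsum(r$lengths))
      gcur <- gstart
      for (k in seq_along(r$values)) {
        if (r$values[k]) {
          segs[[length(segs) + 1L]] <- data.frame(
            block_id = bid, genome = src, msa_start = offset + pos[k],
            length = r$lengths[k], genome_start = gcur,
            stringsAsFactors = FALSE)
          gcur <- gcur + r$lengths[k]
        }
      }
    }
  }
  flush_block()
  msa_blocks(do.call(rbind, blocks), do.call(rbind, segs), genomes)
}
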