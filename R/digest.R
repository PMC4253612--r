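#' Read a genome FASTA
#'
#' Loads a (multi-record) FASTA file, uppercases the sequence and validates
#' the alphabet. Only A, C, G, T and N are accepted.
#'
#' @param path path to a FASTA file.
#' @return a named [Biostrings::DNAStringSet].
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  as_genome(g)
}

#' Coerce to a validated genome object
#'
#' Accepts a named character vector or a `DNAStringSet`; uppercases and
#' checks that sequences use only A/C/G/T/N, that records are non-empty and
#' that chromosome names are unique.
#'
#' @param x named character vector of sequences or a `DNAStringSet`.
#' @return a named [Biostrings::DNAStringSet].
#' @export
as_genome <- function(x) {
  if (is.character(x)) {
    if (is.null(names(x)) || anyNA(names(x)) || any(names(x) == ""))
      stop("genome sequences must be named by chromosome")
    x <- Biostrings::DNAStringSet(toupper(x))
  } else if (methods::is(x, "DNAStringSet")) {
    x <- Biostrings::DNAStringSet(toupper(as.character(x)))
  } else stop("unsupported genome representation")
  if (anyDuplicated(names(x))) stop("duplicate chromosome ids")
  if (any(Biostrings::width(x) == 0)) stop("empty chromosome sequence")
  bad <- grepl("[^ACGTN]", as.character(x))
  if (any(bad))
    stop("sequence contains characters outside {A,C,G,T,N}: ",
         paste(names(x)[bad], collapse = ", "))
  x
}

.cut_offsets <- c(CCGG = 1L, CATG = 4L)

#' Find restriction sites in a genome
#'
#' Scans the forward strand for exact motif occurrences. The HMST-seq
#' motifs CCGG (MspI/HpaII) and CATG (NlaIII) are their own reverse
#' complements, so a single-strand scan finds every site. Windows that
#' contain N never match.
#'
#' @param genome a genome as accepted by [as_genome()].
#' @param motif recognition sequence (e.g. `"CCGG"`).
#' @param cut_offset 0-based offset of the cut position within the motif.
#'   Inferred for CCGG (cut after the first C) and CATG (cut after the G);
#'   required for other motifs.
#' @return data.frame with columns `chrom`, `motif_start` (0-based),
#'   `motif`, `cut_pos` (0-based cut coordinate), sorted by chrom then
#'   position.
#' @examples
#' find_sites(c(chr1 = "ACCGGT"), "CCGG")
#' @export
find_sites <- function(genome, motif, cut_offset = NULL) {
  genome <- as_genome(genome)
  motif <- toupper(motif)
  if (nchar(motif) < 1) stop("motif must be non-empty")
  if (grepl("[^ACGT]", motif)) stop("motif must be over {A,C,G,T}")
  if (is.null(cut_offset)) {
    if (!motif %in% names(.cut_offsets))
      stop("cut_offset must be given for motif ", motif)
    cut_offset <- .cut_offsets[[motif]]
  }
  hits <- Biostrings::vmatchPattern(motif, genome, fixed = TRUE)
  res <- lapply(seq_along(genome), function(i) {
    s <- BiocGenerics::start(hits[[i]])
    if (length(s) == 0) return(NULL)
    data.frame(chrom = names(genome)[i], motif_start = sort(s) - 1L,
               motif = motif, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (is.null(res))
    res <- data.frame(chrom = character(), motif_start = integer(),
                      motif = character(), stringsAsFactors = FALSE)
  res$cut_pos <- res$motif_start + as.integer(cut_offset)
  rownames(res) <- NULL
  res
}

#' Build the HMST-seq virtual tag reference
#'
#' For each MspI (CCGG) site, emits up to two reference tags bounded by the
#' nearest NlaIII (CATG) cut positions: the upstream tag runs from the
#' nearest NlaIII cut strictly left of the MspI cut to the MspI cut, the
#' downstream tag from the MspI cut to the nearest NlaIII cut strictly
#' right of it. A direction with no flanking NlaIII site on that
#' chromosome yields no tag.
#'
#' @param msp_sites data.frame of MspI sites from [find_sites()].
#' @param nla_sites data.frame of NlaIII sites from [find_sites()].
#' @param chrom_len optional named vector of chromosome lengths (used only
#'   for validation).
#' @return data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `anchor_ccgg` (motif_start of the anchoring MspI site),
#'   `direction` (`"upstream"`/`"downstream"`) and `is_unique` (NA until
#'   [mark_uniqueness()] is run).
#' @export
build_virtual_library <- function(msp_sites, nla_sites, chrom_len = NULL) {
  stopifnot(all(c("chrom", "cut_pos") %in% names(msp_sites)),
            all(c("chrom", "cut_pos") %in% names(nla_sites)))
  out <- lapply(split(msp_sites, msp_sites$chrom), function(ms) {
    chrom <- ms$chrom[1]
    nc <- sort(nla_sites$cut_pos[nla_sites$chrom == chrom])
    mc <- sort(ms$cut_pos)
    anchor <- ms$motif_start[order(ms$cut_pos)]
    if (length(nc) == 0) return(NULL)
    iu <- findInterval(mc - 0.5, nc)          # last NlaIII cut < MspI cut
    id <- findInterval(mc + 0.5, nc) + 1L     # first NlaIII cut > MspI cut
    up <- iu >= 1
    dn <- id <= length(nc)
    rbind(
      if (any(up)) data.frame(chrom = chrom, start = nc[iu[up]],
                              end = mc[up], anchor_ccgg = anchor[up],
                              direction = "upstream",
                              stringsAsFactors = FALSE),
      if (any(dn)) data.frame(chrom = chrom, start = mc[dn],
                              end = nc[id[dn]], anchor_ccgg = anchor[dn],
                              direction = "downstream",
                              stringsAsFactors = FALSE)
    )
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), anchor_ccgg = integer(),
                      direction = character(), stringsAsFactors = FALSE)
  out <- out[out$end > out$start, , drop = FALSE]
  if (!is.null(chrom_len)) {
    bad <- out$end > chrom_len[out$chrom]
    if (any(bad)) stop("tag interval beyond chromosome end")
  }
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  out$is_unique <- rep(NA, nrow(out))
  rownames(out) <- NULL
  out
}

#' Flag ambiguous tags in a virtual reference
#'
#' A tag is non-unique when its sequence (or reverse complement) occurs as
#' the sequence of any other tag in the full set; reads from such tags
#' cannot be assigned unambiguously and are excluded downstream.
#'
#' @param tags virtual reference from [build_virtual_library()].
#' @param genome the genome the tags were built from.
#' @return `tags` with the `is_unique` column filled in.
#' @export
mark_uniqueness <- function(tags, genome) {
  genome <- as_genome(genome)
  if (nrow(tags) == 0) return(tags)
  if (!all(tags$chrom %in% names(genome)))
    stop("tag chromosome not present in genome")
  len <- setNames(Biostrings::width(genome), names(genome))
  if (any(tags$start < 0) || any(tags$end > len[tags$chrom]))
    stop("tag interval outside chromosome bounds")
  seqs <- extract_tag_seqs(tags, genome)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs)))
  canon <- ifelse(seqs <= rc, seqs, rc)
  dup <- canon %in% canon[duplicated(canon)]
  tags$is_unique <- !dup
  tags
}

extract_tag_seqs <- function(tags, genome) {
  vapply(seq_len(nrow(tags)), function(i) {
    as.character(Biostrings::subseq(genome[[tags$chrom[i]]],
                                    start = tags$start[i] + 1L,
                                    end = tags$end[i]))
  }, character(1))
}

#' Write the virtual reference to FASTA and BED
#'
#' FASTA headers follow `chrom:start-end:direction`; the BED6 name column
#' carries the anchoring CCGG motif position.
#'
#' @param tags virtual reference (ideally after [mark_uniqueness()]).
#' @param genome source genome.
#' @param out_prefix path prefix; writes `<prefix>.fa` and `<prefix>.bed`.
#' @return invisibly, the two paths written.
#' @export
write_virtual_reference <- function(tags, genome, out_prefix) {
  genome <- as_genome(genome)
  seqs <- Biostrings::DNAStringSet(extract_tag_seqs(tags, genome))
  names(seqs) <- sprintf("%s:%d-%d:%s", tags$chrom, tags$start, tags$end,
                         tags$direction)
  fa <- paste0(out_prefix, ".fa")
  bed <- paste0(out_prefix, ".bed")
  Biostrings::writeXStringSet(seqs, fa)
  write.table(
    data.frame(tags$chrom, tags$start, tags$end, tags$anchor_ccgg, 0L, "+"),
    bed, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(c(fa, bed))
}
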