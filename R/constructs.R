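## Peptide constructs of the septin Cdc12 C-terminal region.
##
## The extended AH is assembled from four canonical segments: an 8-residue
## N-terminal flank, the 18-residue amphipathic-helix core, an 8-residue
## C-terminal flank, and (for tandem constructs) a 10-residue GS-rich linker.
## "Flipping" a domain in CN-NC constructs means reversing its residue order;
## no D-amino-acid chemistry is implied.

.segments <- list(
  n_flank = "ERIRLNGD",
  ah_core = "LEEIQGKVKKLEEQVKSL",
  c_flank = "QVKKSHLK",
  linker  = "GSGSRSGSGS")

.reverse_seq <- function(s)
  paste(rev(strsplit(s, "")[[1]]), collapse = "")

.valid_aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Assemble a peptide construct
#'
#' Builds one of the four construct sequences from the canonical segments:
#' \describe{
#'   \item{extended_AH}{N-flank + AH core + C-flank (34 residues).}
#'   \item{tandem_NC_NC}{AH core + linker + AH core (46 residues), the
#'     head-to-tail tandem.}
#'   \item{tandem_CN_NC}{reversed AH core + linker + AH core (46 residues),
#'     the palindromic tandem with the first domain flipped.}
#'   \item{tandem_extended_CN_NC}{reversed (AH core + C-flank) + linker +
#'     AH core + C-flank (62 residues), the palindromic tandem carrying the
#'     charged C-terminal extensions on both ends.}
#' }
#'
#' @param name construct name, one of the four above.
#' @param nCap,cCap terminal treatment, \code{"neutral"} (capped, no terminal
#'   charge; the simulation default) or \code{"free"} (+1 at the N-terminus,
#'   -1 at the C-terminus).
#' @return A list of class \code{ConstructSpec} with elements \code{name},
#'   \code{sequence}, \code{regions} (a \linkS4class{PeptideRegions} for the
#'   34-mer, NULL otherwise), \code{n_cap}, \code{c_cap}, \code{net_charge}.
#' @examples
#' buildConstruct("extended_AH")$sequence
#' @export
buildConstruct <- function(name = c("extended_AH", "tandem_NC_NC",
                                    "tandem_CN_NC", "tandem_extended_CN_NC"),
                           nCap = "neutral", cCap = "neutral") {
  name <- match.arg(name)
  s <- .segments
  sequence <- switch(name,
    extended_AH = paste0(s$n_flank, s$ah_core, s$c_flank),
    tandem_NC_NC = paste0(s$ah_core, s$linker, s$ah_core),
    tandem_CN_NC = paste0(.reverse_seq(s$ah_core), s$linker, s$ah_core),
    tandem_extended_CN_NC = paste0(.reverse_seq(paste0(s$ah_core, s$c_flank)),
                                   s$linker, s$ah_core, s$c_flank))
  regions <- if (name == "extended_AH") PeptideRegions() else NULL
  structure(list(name = name, sequence = sequence, regions = regions,
                 n_cap = nCap, c_cap = cCap,
                 net_charge = netCharge(sequence, nCap = nCap, cCap = cCap)),
            class = "ConstructSpec")
}

#' @export
print.ConstructSpec <- function(x, ...) {
  cat(sprintf("Construct %s: %d residues, net charge %+d (%s N-cap, %s C-cap)\n",
              x$name, nchar(x$sequence), x$net_charge, x$n_cap, x$c_cap))
  cat(" ", x$sequence, "\n")
  invisible(x)
}

#' Net charge of a peptide sequence
#'
#' Integer charge model at pH 7.4: side chains D/E -1, K/R +1, histidine
#' neutral; a free N-terminus adds +1 and a free C-terminus adds -1, while
#' neutral capping (the simulation setup) contributes nothing.  The model is
#' additive over concatenation when junction termini are capped.
#'
#' @param sequence one-letter amino-acid string (standard 20 codes).
#' @param nCap,cCap \code{"neutral"} or \code{"free"}.
#' @return Integer net charge in elementary charge units.
#' @examples
#' netCharge("QVKKSHLK")   # +3: the C-terminal flank of the extended AH
#' @export
netCharge <- function(sequence, nCap = "neutral", cCap = "neutral") {
  aa <- strsplit(toupper(sequence), "")[[1]]
  if (length(aa) && !all(aa %in% .valid_aa))
    stop("input error: unknown residue letter(s): ",
         paste(unique(aa[!aa %in% .valid_aa]), collapse = ", "))
  side <- sum(aa %in% c("K", "R")) - sum(aa %in% c("D", "E"))
  term <- 0L
  if (length(aa)) {
    if (match.arg(nCap, c("neutral", "free")) == "free") term <- term + 1L
    if (match.arg(cCap, c("neutral", "free")) == "free") term <- term - 1L
  }
  as.integer(side + term)
}

#' Classify residues by chemical class
#'
#' Four-way classification used for residue-class contact statistics:
#' acidic \{D, E\}; basic \{K, R, H\}; polar \{S, T, N, Q, C, Y, G\};
#' hydrophobic \{A, V, L, I, M, F, W, P\}.
#'
#' @param code character vector of one-letter residue codes.
#' @return Character vector of classes (vectorised over \code{code}).
#' @examples
#' classifyResidue(c("E", "K", "S", "L"))
#' @export
classifyResidue <- function(code) {
  code <- toupper(code)
  bad <- !code %in% .valid_aa
  if (any(bad))
    stop("input error: invalid residue code(s): ",
         paste(unique(code[bad]), collapse = ", "))
  cls <- character(length(code))
  cls[code %in% c("D", "E")] <- "acidic"
  cls[code %in% c("K", "R", "H")] <- "basic"
  cls[code %in% c("S", "T", "N", "Q", "C", "Y", "G")] <- "polar"
  cls[code %in% c("A", "V", "L", "I", "M", "F", "W", "P")] <- "hydrophobic"
  cls
}

#' Per-residue class/charge table of a construct
#'
#' @param construct a \code{ConstructSpec} from \code{\link{buildConstruct}}.
#' @return data.frame with columns \code{residue_index}, \code{code},
#'   \code{class}, \code{charge}.
#' @export
residueTable <- function(construct) {
  aa <- strsplit(construct$sequence, "")[[1]]
  data.frame(residue_index = seq_along(aa), code = aa,
             class = classifyResidue(aa),
             charge = ifelse(aa %in% c("K", "R"), 1L,
                             ifelse(aa %in% c("D", "E"), -1L, 0L)),
             stringsAsFactors = FALSE)
}

#' Export constructs as FASTA
#'
#' @param constructs a list of \code{ConstructSpec} objects (or one).
#' @param path output FASTA path.
#' @return Invisibly, \code{path}.
#' @export
constructsToFasta <- function(constructs, path) {
  if (inherits(constructs, "ConstructSpec")) constructs <- list(constructs)
  seqs <- Biostrings::AAStringSet(vapply(constructs, `[[`, "", "sequence"))
  names(seqs) <- vapply(constructs, `[[`, "", "name")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
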