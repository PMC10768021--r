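# Amino-acid alphabet and hydrophobicity scales used across the package.
# X (unknown residue) is tolerated in sequences but never satisfies a motif
# position class and contributes a neutral 0 to both hydrophobicity scales.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Kyte & Doolittle (1982) hydropathy, used for transmembrane detection.
KYTE_DOOLITTLE <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2,
  X =  0.0
)

# Eisenberg consensus hydrophobicity, used for the hydrophobic moment.
EISENBERG <- c(
  A =  0.62, R = -2.53, N = -0.78, D = -0.90, C =  0.29,
  Q = -0.85, E = -0.74, G =  0.48, H = -0.40, I =  1.38,
  L =  1.06, K = -1.50, M =  0.64, F =  1.19, P =  0.12,
  S = -0.18, T = -0.05, W =  0.81, Y =  0.26, V =  1.08,
  X =  0.00
)

# Coerce a protein_record or character scalar to a bare upper-case sequence.
as_aa_sequence <- function(x) {
  if (inherits(x, "protein_record")) x <- x$sequence
  if (!is.character(x) || length(x) != 1L) {
    stop("expected a single protein sequence or a protein_record")
  }
  toupper(x)
}

aa_chars <- function(sequence) {
  if (nchar(sequence) == 0L) return(character(0))
  strsplit(sequence, "", fixed = TRUE)[[1]]
}
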