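#' Configuration of the in-silico random circle null
#'
#' @param nPerDataset integer vector: circles per dataset, matched
#'   one-to-one to the observed samples.
#' @param sizeMin,sizeMax circle size bounds in bp (default 150-850,
#'   bracketing the dominant observed size range).
#' @param seed RNG seed.
#' @return list of class \code{NullConfig}.
#' @export
nullConfig <- function(nPerDataset, sizeMin = 150L, sizeMax = 850L,
                       seed = 1L) {
    if (sizeMin >= sizeMax) stop("sizeMin must be < sizeMax")
    if (!length(nPerDataset) || any(nPerDataset < 1))
        stop("nPerDataset must be positive counts")
    structure(list(nDatasets = length(nPerDataset),
                   nPerDataset = as.integer(nPerDataset),
                   sizeMin = as.integer(sizeMin),
                   sizeMax = as.integer(sizeMax),
                   seed = as.integer(seed)),
              class = "NullConfig")
}

#' Generate chromosome-length-weighted random circle datasets
#'
#' The expectation baseline for enrichment statistics: for each dataset,
#' each circle's chromosome is drawn with probability proportional to
#' chromosome length, its start uniformly on the chromosome and its size
#' uniformly on [sizeMin, sizeMax]. Circles running past the chromosome end
#' are resampled (size distribution preserved, not clipped). Deterministic
#' per seed.
#'
#' @param config a \code{\link{nullConfig}}.
#' @param genome named DNAStringSet or named chromosome-length vector.
#' @return list of GRanges, one per dataset.
#' @examples
#' sets <- generateInsilico(nullConfig(c(100, 100), seed = 7),
#'                          c(chr1 = 3e5, chr2 = 1e5))
#' range(width(sets[[1]]))
#' @export
generateInsilico <- function(config, genome) {
    stopifnot(inherits(config, "NullConfig"))
    seqlens <- genomeSeqlengths(genome)
    tooShort <- which(as.numeric(seqlens) < config$sizeMax)
    if (length(tooShort))
        stop("sizeMax exceeds chromosome length: ",
             paste(names(seqlens)[tooShort], collapse = ", "))
    withSeed(config$seed, lapply(config$nPerDataset, function(n) {
        chrom <- sample(names(seqlens), n, replace = TRUE,
                        prob = as.numeric(seqlens))
        size <- sample(seq(config$sizeMin, config$sizeMax), n, replace = TRUE)
        s0 <- integer(n)
        for (i in seq_len(n)) {
            L <- seqlens[[chrom[i]]]
            repeat {
                cand <- as.integer(floor(runif(1, 0, L)))
                if (cand + size[i] <= L) { s0[i] <- cand; break }
            }
        }
        grFrom0(chrom, s0, s0 + size, seqlens = seqlens)
    }))
}
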