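#' @importFrom BiocGenerics counts
NULL

#' Total number of counted codons
#' @param x A CodonUsageTable.
#' @return Integer: sum of all sense-codon counts.
#' @export
setGeneric("totalCodons", function(x) standardGeneric("totalCodons"))

#' Number of codons skipped because they contained N
#' @param x A CodonUsageTable.
#' @export
setGeneric("skipped", function(x) standardGeneric("skipped"))

#' Marker table of a genetic map
#' @param x A GeneticMap.
#' @export
setGeneric("mapMarkers", function(x) standardGeneric("mapMarkers"))

#' Gene identifiers
#' @param x A GeneModelSet or SyntheticGenome.
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' Transcription-unit ranges
#' @param x A GeneModelSet.
#' @export
setGeneric("transcriptionUnits", function(x) standardGeneric("transcriptionUnits"))

#' CDS / intron / flank intervals of a model set
#' @param x A GeneModelSet.
#' @name model-intervals
#' @export
setGeneric("cdsIntervals", function(x) standardGeneric("cdsIntervals"))

#' @rdname model-intervals
#' @export
setGeneric("intronIntervals", function(x) standardGeneric("intronIntervals"))

#' @rdname model-intervals
#' @export
setGeneric("flankIntervals", function(x) standardGeneric("flankIntervals"))

#' Mono- and multi-isoacceptor amino acids of a partition
#' @param x An IsoacceptorPartition.
#' @name partition-accessors
#' @export
setGeneric("monoAminoAcids", function(x) standardGeneric("monoAminoAcids"))

#' @rdname partition-accessors
#' @export
setGeneric("multiAminoAcids", function(x) standardGeneric("multiAminoAcids"))

#' Per-step table of a variance partition
#' @param x A VariancePartition.
#' @export
setGeneric("partitionTable", function(x) standardGeneric("partitionTable"))

#' Profile table of a metagene profile
#' @param x A MetageneProfile.
#' @export
setGeneric("profileTable", function(x) standardGeneric("profileTable"))

#' Per-gene generative truth of a simulation
#' @param x A SyntheticGenome.
#' @export
setGeneric("truthTable", function(x) standardGeneric("truthTable"))

#' Gene models of a simulation
#' @param x A SyntheticGenome.
#' @export
setGeneric("geneModels", function(x) standardGeneric("geneModels"))
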