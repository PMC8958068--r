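#' Registry of the 105 radiomic features
#'
#' Canonical snake_case feature names, their class (shape, firstorder, glcm,
#' glrlm, glszm, gldm, ngtdm) and human-readable labels. Class sizes are
#' 14 / 18 / 22 / 16 / 16 / 14 / 5.
#'
#' @return A data frame with columns `name`, `class`, `label`.
#' @export
feature_registry <- function() {
  snake <- function(x) gsub("[^a-z0-9]+", "_", tolower(x))
  mk <- function(class, labels)
    data.frame(name = paste(class, snake(labels), sep = "_"),
               class = class, label = labels, stringsAsFactors = FALSE)
  shape <- mk("shape", c(
    "Elongation", "Flatness", "Least axis length", "Major axis length",
    "Maximum 2D diameter column", "Maximum 2D diameter row",
    "Maximum 2D diameter slice", "Maximum 3D diameter", "Mesh volume",
    "Minor axis length", "Sphericity", "Surface area", "Surface volume ratio",
    "Voxel volume"))
  fo <- mk("firstorder", c(
    "10 percentile", "90 percentile", "Energy", "Entropy",
    "Interquartile range", "Kurtosis", "Maximum", "Mean absolute deviation",
    "Mean", "Median", "Minimum", "Range", "Robust mean absolute deviation",
    "Root mean squared", "Skewness", "Total energy", "Uniformity", "Variance"))
  glcm <- mk("glcm", c(
    "Autocorrelation", "Joint average", "Cluster prominence", "Cluster shade",
    "Cluster tendency", "Contrast", "Correlation", "Difference average",
    "Difference entropy", "Difference variance", "Joint energy",
    "Joint entropy", "Imc1", "Imc2", "Idm", "Idmn", "Id", "Idn",
    "Inverse variance", "Maximum probability", "Sum entropy", "Sum squares"))
  glrlm <- mk("glrlm", c(
    "Gray level nonuniformity", "Gray level nonuniformity normalized",
    "Gray level variance", "High gray level run emphasis", "Long run emphasis",
    "Long run high gray level emphasis", "Long run low gray level emphasis",
    "Low gray level run emphasis", "Run entropy", "Run length nonuniformity",
    "Run length nonuniformity normalized", "Run percentage", "Run variance",
    "Short run emphasis", "Short run high gray level emphasis",
    "Short run low gray level emphasis"))
  glszm <- mk("glszm", c(
    "Gray level nonuniformity", "Gray level nonuniformity normalized",
    "Gray level variance", "High gray level zone emphasis",
    "Large area emphasis", "Large area high gray level emphasis",
    "Large area low gray level emphasis", "Low gray level zone emphasis",
    "Size zone nonuniformity", "Size zone nonuniformity normalized",
    "Small area emphasis", "Small area high gray level emphasis",
    "Small area low gray level emphasis", "Zone entropy", "Zone percentage",
    "Zone variance"))
  gldm <- mk("gldm", c(
    "Dependence entropy", "Dependence nonuniformity",
    "Dependence nonuniformity normalized", "Dependence variance",
    "Gray level nonuniformity", "Gray level variance",
    "High gray level emphasis", "Large dependence emphasis",
    "Large dependence high gray level emphasis",
    "Large dependence low gray level emphasis", "Low gray level emphasis",
    "Small dependence emphasis", "Small dependence high gray level emphasis",
    "Small dependence low gray level emphasis"))
  ngtdm <- mk("ngtdm", c(
    "Busyness", "Coarseness", "Complexity", "Contrast", "Strength"))
  rbind(shape, fo, glcm, glrlm, glszm, gldm, ngtdm)
}
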