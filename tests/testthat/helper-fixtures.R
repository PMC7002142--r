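## shared helpers for the test suite

## random z-scored samples x analytes matrix
randZ <- function(n, p, seed) {
  set.seed(seed)
  m <- matrix(stats::rnorm(n * p), n, p,
              dimnames = list(sprintf("S%02d", seq_len(n)),
                              sprintf("A%02d", seq_len(p))))
  plexsig:::zscoreMatrix(m)
}

## quick PanelExperiment around a samples x analytes matrix
quickPanel <- function(values, groups, batch = NULL, panelLabels = NULL,
                       zscored = FALSE) {
  sd <- data.frame(sample_id = rownames(values), group = groups)
  if (!is.null(batch)) sd$batch <- batch
  ad <- if (is.null(panelLabels)) NULL else
    data.frame(name = colnames(values), panel = panelLabels,
               in_linear_range = TRUE)
  PanelExperiment(values, sampleData = sd, analyteData = ad,
                  zscored = zscored)
}

## a simple null design: k groups x n, p analytes, optional planted pieces
nullDesign <- function(seed, nGroups = 4L, n = 6L, p = 16L, nBatches = 1L) {
  PanelDesign(paste0("g", seq_len(nGroups)), n,
              sprintf("A%02d", seq_len(p)), nBatches = nBatches,
              seed = seed)
}

## build a valid PlsdaModel by hand (for tie-break / rotation tests)
handModel <- function(loadings, scores, groups) {
  methods::new("PlsdaModel", loadings = loadings, scores = scores,
               groups = droplevels(as.factor(groups)),
               nLv = ncol(loadings), rotationAngle = 0,
               contrast = NA_character_,
               separation = rep(NA_real_, ncol(loadings)),
               separationCapped = rep(FALSE, ncol(loadings)))
}
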