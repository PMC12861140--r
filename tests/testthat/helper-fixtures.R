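# Shared fixture builders. All synthetic inputs are generated in code with
# fixed seeds; nothing is read from disk unless a test writes it first.

# A small frame with a flat bright bar (rows barRows) on a dark background;
# used where full phantom geometry is not needed.
barFrame <- function(h = 80, w = 120, barRows = 20:40, value = 100,
                     background = 0) {
  img <- matrix(background, h, w)
  img[barRows, ] <- value
  ScheimpflugFrame(img)
}

# Batch of phantom specs spanning the generator's geometry ranges,
# deterministic in `n` and `seed`.
phantomBatch <- function(n = 20, seed = 101) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    h <- sample(120:200, 1); w <- sample(260:360, 1)
    phantomSpec(
      width = w, height = h,
      apexRow = sample(round(0.08 * h):round(0.16 * h), 1),
      thickness = sample(round(0.12 * h):round(0.20 * h), 1),
      edgeRise = sample(round(0.05 * h):round(0.12 * h), 1),
      corneaMean = runif(1, 40, 60), corneaSd = runif(1, 2, 4),
      irisBase = runif(1, 22, 34), lateralBase = runif(1, 22, 34),
      artefactFractionIris = runif(1, 0, 0.05),
      artefactFractionLateral = runif(1, 0, 0.05),
      seed = seed + i)
  })
}

# Two-eyes-per-subject records with known fixed-effect slope.
lmmRecords <- function(nSubjects = 50, beta0 = 1.5, subjectSd = 1,
                       residSd = 1, seed = 1) {
  set.seed(seed)
  subjectId <- rep(sprintf("S%03d", seq_len(nSubjects)), each = 2)
  x <- rnorm(2 * nSubjects)
  u <- rep(rnorm(nSubjects, 0, subjectSd), each = 2)
  data.frame(subjectId = subjectId, x = x,
             y = 2 + beta0 * x + u + rnorm(2 * nSubjects, 0, residSd))
}
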