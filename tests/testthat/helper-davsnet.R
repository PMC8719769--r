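# Shared fixtures, built in code at test time.

canonical_graph <- function() build_davsnet_graph(tensor_shape(640L, 640L, 3L))

# A small model + random image/target pair on an n x n grid (n divisible by 8).
tiny_case <- function(n = 16L, seed = 101L) {
  set.seed(seed)
  list(
    model = init_davsnet(seed = seed, input_size = n),
    image = array(runif(n * n * 3), c(n, n, 3)),
    target = matrix(rbinom(n * n, 1, 0.3), n, n)
  )
}

# Brute-force per-pixel confusion tally (the exhaustive oracle).
confusion_oracle <- function(pred, truth, fov = NULL) {
  if (is.null(fov)) fov <- matrix(1L, nrow(truth), ncol(truth))
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_len(nrow(truth))) {
    for (j in seq_len(ncol(truth))) {
      if (fov[i, j] != 1) next
      if (pred[i, j] == 1 && truth[i, j] == 1) tp <- tp + 1L
      if (pred[i, j] == 1 && truth[i, j] == 0) fp <- fp + 1L
      if (pred[i, j] == 0 && truth[i, j] == 0) tn <- tn + 1L
      if (pred[i, j] == 0 && truth[i, j] == 1) fn <- fn + 1L
    }
  }
  c(tp = tp, fp = fp, tn = tn, fn = fn)
}

# Mann-Whitney concordance oracle for ROC-AUC: P(random vessel pixel
# outscores a random background pixel), ties counted 0.5.
roc_auc_oracle <- function(scores, truth) {
  pos <- scores[truth == 1]; neg <- scores[truth == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Exhaustive threshold-sweep oracle for average precision (precision at zero
# predicted positives defined as 1).
pr_auc_oracle <- function(scores, truth) {
  thr <- sort(unique(scores), decreasing = TRUE)
  npos <- sum(truth == 1)
  prev_recall <- 0
  ap <- 0
  for (t in thr) {
    sel <- scores >= t
    prec <- sum(truth[sel] == 1) / sum(sel)
    rec <- sum(truth[sel] == 1) / npos
    ap <- ap + (rec - prev_recall) * prec
    prev_recall <- rec
  }
  ap
}

# Toy-size generator settings: at 16-32 px the default vessel-fraction world
# (3-15% of the FOV, realistic at >= 48 px) is infeasible, so toy fixtures
# relax the bounds and thin the tree. Used only where image content is
# incidental to what the test checks.
toy_params <- function(...) {
  synth_params(branch_depth = 3L, initial_caliber = 1,
               vessel_fraction_range = c(0.005, 0.6), ...)
}

toy_sample <- function(n, seed) generate_fundus_sample(n, toy_params(), seed = seed)

toy_dataset <- function(n, size, seed) {
  generate_fundus_dataset(n, size, toy_params(), seed = seed)
}
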