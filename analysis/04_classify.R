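#!/usr/bin/env Rscript

# Source classification: mean-thresholded binary features, 60/40
# stratified split, city-block KNN with k = 1; shuffled-label control;
# PCA embedding; unsupervised k-medoids clustering of the 4-class session
# and of a tibial/peroneal session.

library(ecaptools)

session <- list(
  recording = read_recording("results/session_seed1.rec"),
  events = read_events("results/session_seed1_events.csv"))
feats <- session_features(session)

res <- classify_session(feats$map, feats$labels, seed = 1)
print(res)
write.csv(as.data.frame.matrix(res$confusion), "results/confusion_matrix.csv")

feat <- binarize(feats$map)
set.seed(2)
shuffled <- vapply(1:50, function(i) {
  yl <- sample(feats$labels)
  sp <- split_stratified(yl, 0.60, seed = i)
  knn_classify(feat[sp$train, ], yl[sp$train], feat[sp$test, ],
               test_y = yl[sp$test])$accuracy
}, numeric(1))
cat(sprintf("shuffled-label control: mean accuracy %.1f%% (chance 25%%)\n",
            100 * mean(shuffled)))

pc <- reduce_pca(feats$map, 2)
cat(sprintf("PCA: first two components carry %.1f%% of the variance\n",
            100 * sum(attr(pc, "variance_ratio"))))

cl4 <- cluster_sources(feat, 4, seed = 1, true_labels = feats$labels)
cat(sprintf("k-medoids (k = 4) agreement with true sources: %.1f%%\n",
            100 * cl4$agreement))

cfg2 <- default_session_config(sample_rate = 10000, duration_s = 40,
                               labels = c("TIBIAL", "PERONEAL"), seed = 5)
f2 <- session_features(simulate_session(cfg2))
cl2 <- cluster_sources(binarize(f2$map), 2, seed = 1,
                       true_labels = f2$labels)
cat(sprintf("k-medoids (k = 2), tibial vs peroneal: %.1f%% agreement\n",
            100 * cl2$agreement))

summary <- list(accuracy = res$accuracy,
                per_class_loss = as.list(res$per_class_loss),
                shuffled_mean_accuracy = mean(shuffled),
                kmedoids4_agreement = cl4$agreement,
                kmedoids2_agreement = cl2$agreement, split_seed = 1)
jsonlite::write_json(summary, "results/classification_summary.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
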