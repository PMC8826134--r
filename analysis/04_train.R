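#!/usr/bin/env Rscript
# Stage 4 - architecture search and final training.
#
# Runs a reduced grid search (a corner of the full 216-configuration
# 16..512 x 16..512 x dropout 0.2..0.7 grid, to keep this driver quick)
# on a fixed 70/30 split with early stopping on validation AUC, then
# trains the selected configuration and stores the model as a portable
# text container. The full grid is enumerable via grid_spec(); training
# all 216 configurations is a compute decision, not a code path change.

suppressPackageStartupMessages(library(rotorrisk))
out <- "results/model"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

tab <- read.table("results/features/feature_table.tsv", sep = "\t",
                  header = TRUE, check.names = FALSE)
feats <- as.matrix(tab[, feature_names()])
labels <- tab$label

base <- model_config(batch_size = 512, max_epochs = 30, patience = 5,
                     seed = 11)
gs <- grid_search(feats, labels, grid_spec(c(32, 64), c(16, 32), c(0.3, 0.4)),
                  base_cfg = base, split_seed = 2)
write.table(gs, file.path(out, "grid_search.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
best <- gs[1, ]
message(sprintf("best of %d configurations: %d/%d units, dropout %.1f (val AUC %.3f)",
                nrow(gs), best$units1, best$units2, best$dropout_rate,
                best$val_auc))

cfg <- model_config(units1 = best$units1, units2 = best$units2,
                    dropout_rate = best$dropout_rate, batch_size = 512,
                    max_epochs = 60, patience = 10, seed = 11)
tr <- split_train_val(nrow(feats), seed = 2)
ns <- fit_normalizer(feats[tr, , drop = FALSE])
xz <- apply_normalizer(feats, ns)
fit <- train_network(init_network(cfg), xz[tr, ], labels[tr],
                     xz[!tr, ], labels[!tr], cfg)
model <- fit$model
model$norm_stats <- ns
write_model(model, file.path(out, "model.txt"))
write.table(fit$log, file.path(out, "train_log.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)

bayes <- as.numeric(readLines("results/world/bayes_auc.txt"))
tr_auc <- auc(labels[tr], predict(model, xz[tr, ]))
va_auc <- auc(labels[!tr], predict(model, xz[!tr, ]))
message(sprintf("final model: train AUC %.3f, validation AUC %.3f (Bayes ceiling %.3f)",
                tr_auc, va_auc, bayes))
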