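#!/usr/bin/env Rscript
# Stage 5: relative importance of the four environmental inputs.
#
# Builds the working station-hour feature/target table from the linked
# synthetic events, trains the 4-9-2 logistic network on a 70% split, and
# decomposes its connection weights into normalized per-input importances.

library(comfortrisk)

climate <- readr::read_csv("scratch/registry/climate.csv",
                           show_col_types = FALSE)
linked <- readr::read_csv("scratch/registry/linked.csv",
                          show_col_types = FALSE)

tbl <- build_dataset(linked, climate, encoding = "count")
message(format(nrow(tbl), big.mark = ","), " working station-hours")

model <- train_network(tbl, network_spec(seed = 7L))
print(model)

imp <- garson_importance(model)
imp$importance <- round(imp$importance, 4)
readr::write_csv(imp, "results/tables/importance.csv")
message("relative importance: ",
        paste(sprintf("%s %.4f", imp$variable, imp$importance),
              collapse = ", "))

diag <- data.frame(r2 = model$r2, final_loss = model$final_loss,
                   converged = model$converged,
                   hidden_units = model$spec$hidden_units,
                   train_fraction = model$spec$train_fraction)
readr::write_csv(diag, "results/tables/importance_diagnostics.csv")
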