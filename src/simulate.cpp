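#include <Rcpp.h>
using namespace Rcpp;

// Daily blood-bank inventory model over a horizon. Mirrors the R-level
// step_day()/order_quantity() pair exactly; kept in C++ because the policy
// grid search runs it tens of thousands of times.
//
// u: realized demand; p2/p4: demand forecasts for the next 2/4 days;
// wd: weekday index, Sunday = 0 .. Saturday = 6.
// [[Rcpp::export]]
List simulate_inventory_cpp(IntegerVector u, NumericVector p2,
                            NumericVector p4, IntegerVector wd,
                            int alpha, int beta, int gamma,
                            int fixed_order = -1) {
  int n = u.size();
  IntegerVector order(n), arrival(n), purchase(n), waste(n), stock(n), t4v(n);

  int r1 = 0, r2 = 0, r3 = 0;   // end-of-day stock by remaining shelf life
  int om1 = 0, om2 = 0;          // orders placed 1 and 2 days ago

  for (int i = 0; i < n; ++i) {
    // init: age the stock, receive the order placed two days ago
    int a0 = r1, a1 = r2, a2 = r3, a3 = om2;
    arrival[i] = om2;

    // oldest-first consumption via cumulative balances
    int t1 = a0 - u[i];
    int t2 = a1 + t1;
    int t3 = a2 + t2;
    int t4 = a3 + t3;
    int w = t1 > 0 ? t1 : 0;
    a1 = std::min(std::max(t2, 0), a1);
    a2 = std::min(std::max(t3, 0), a2);
    a3 = std::min(std::max(t4, 0), a3);

    // emergency purchase when the balance falls to or below beta
    int b = 0;
    if (t4 <= beta) {
      b = gamma - t4;
      if (b < 0) b = 0;
      int deficit = t4 < 0 ? -t4 : 0;
      int surplus = b - deficit;
      if (surplus > 0) a3 += surplus;
    }

    int s = a1 + a2 + a3;

    // end-of-day production order
    int o = 0;
    if (wd[i] <= 4) {
      if (fixed_order >= 0) {
        o = fixed_order;  // constant-order baseline: no stock feedback
      } else {
        double P = (wd[i] == 4) ? p4[i] : p2[i];
        double raw = P + alpha - s - om1;
        if (raw > 0) o = (int)std::floor(raw + 0.5);
      }
    }

    purchase[i] = b;
    waste[i] = w;
    stock[i] = s;
    order[i] = o;
    t4v[i] = t4;

    r1 = a1; r2 = a2; r3 = a3;
    om2 = om1;
    om1 = o;
  }

  return List::create(_["order"] = order, _["arrival"] = arrival,
                      _["purchase"] = purchase, _["waste"] = waste,
                      _["stock"] = stock, _["t4"] = t4v);
}

// Summary-only variant for the grid search: returns total purchases and
// waste over the post-warmup horizon.
// [[Rcpp::export]]
NumericVector simulate_totals_cpp(IntegerVector u, NumericVector p2,
                                  NumericVector p4, IntegerVector wd,
                                  int alpha, int beta, int gamma,
                                  int warmup, int fixed_order = -1) {
  int n = u.size();
  long total_b = 0, total_w = 0, total_u = 0, total_o = 0;
  int r1 = 0, r2 = 0, r3 = 0, om1 = 0, om2 = 0;

  for (int i = 0; i < n; ++i) {
    int a0 = r1, a1 = r2, a2 = r3, a3 = om2;
    int t1 = a0 - u[i];
    int t2 = a1 + t1;
    int t3 = a2 + t2;
    int t4 = a3 + t3;
    int w = t1 > 0 ? t1 : 0;
    a1 = std::min(std::max(t2, 0), a1);
    a2 = std::min(std::max(t3, 0), a2);
    a3 = std::min(std::max(t4, 0), a3);
    int b = 0;
    if (t4 <= beta) {
      b = gamma - t4;
      if (b < 0) b = 0;
      int deficit = t4 < 0 ? -t4 : 0;
      int surplus = b - deficit;
      if (surplus > 0) a3 += surplus;
    }
    int s = a1 + a2 + a3;
    int o = 0;
    if (wd[i] <= 4) {
      if (fixed_order >= 0) {
        o = fixed_order;  // constant-order baseline: no stock feedback
      } else {
        double P = (wd[i] == 4) ? p4[i] : p2[i];
        double raw = P + alpha - s - om1;
        if (raw > 0) o = (int)std::floor(raw + 0.5);
      }
    }
    if (i >= warmup) {
      total_b += b; total_w += w; total_u += u[i]; total_o += o;
    }
    r1 = a1; r2 = a2; r3 = a3;
    om2 = om1; om1 = o;
  }
  return NumericVector::create(
      _["total_used"] = (double)total_u, _["total_ordered"] = (double)total_o,
      _["total_purchased"] = (double)total_b, _["total_wasted"] = (double)total_w);
}
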