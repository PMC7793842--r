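# Standalone interactive HTML rendering. The page embeds the graph as JSON
# and draws it with a small amount of inline SVG/JavaScript: feature-vector
# strip on top (boxes coloured by interaction type), nodes in feature-count
# columns, cover edges, hover tooltips with the node's features and count,
# and two-node selection that highlights the intersection (meet) node —
# which always exists in the graph when the intersection is non-empty.

feature_type_colors <- c(H = "#f2c14e", HBA = "#d7263d", HBD = "#2a9d34",
                         AR = "#1f77b4", PI = "#7b2cbf", NI = "#9d4edd",
                         XBD = "#6c757d")

#' Render a graph as a standalone interactive HTML page
#'
#' @param graph An `hgpm_graph` with layout assigned (see
#'   [assign_layout()]).
#' @param path Output HTML path.
#' @param color_by Optional named numeric metric (node_id -> value in
#'   `[0, 1]`, e.g. per-node screening AUC); nodes are then coloured on a
#'   red-green ramp and artificial nodes gray. Default colouring is blue
#'   for observed, orange for artificial, green for reference nodes.
#' @param label_nodes Draw node ids next to the markers.
#' @param jitter_seed Optional integer; adds a small seeded vertical jitter
#'   for very dense graphs.
#' @return `path`, invisibly.
#' @export
render_html <- function(graph, path, color_by = NULL, label_nodes = FALSE,
                        jitter_seed = NULL) {
  nodes <- graph$nodes
  if (is.null(nodes$x) || is.null(nodes$y)) {
    hgpm_stop("hgpm_layout_error",
              "graph has no layout; run assign_layout() first")
  }
  y <- nodes$y
  if (!is.null(jitter_seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(as.integer(jitter_seed))
    span <- max(diff(range(y)), 1)
    y <- y + stats::runif(length(y), -0.01, 0.01) * span
  }
  if (is.null(color_by)) {
    col <- c(observed = "#1f77b4", artificial = "#ff7f0e",
             reference = "#2a9d34")[nodes$origin]
  } else {
    col <- color_by_metric(graph, color_by)$color
  }
  types <- sub("\\|.*$", "", graph$catalog$entries)
  strip <- data.frame(serial = graph$catalog$entries,
                      color = unname(feature_type_colors[types]),
                      stringsAsFactors = FALSE)
  payload <- jsonlite::toJSON(list(
    nodes = data.frame(id = nodes$node_id, pattern = nodes$pattern,
                       x = nodes$x, y = y, size = nodes$size,
                       count = nodes$appearance_count, origin = nodes$origin,
                       color = unname(col), stringsAsFactors = FALSE),
    edges = graph$edges,
    catalog = strip,
    variance = graph$metadata$variance_percent %||% NA_real_),
    auto_unbox = TRUE, digits = I(17), null = "null")

  html <- paste0(
    "<!DOCTYPE html>\n<html><head><meta charset=\"utf-8\">",
    "<title>Hierarchical graph of pharmacophore models</title>\n",
    "<style>body{font-family:sans-serif;margin:12px} .node{cursor:pointer;stroke:#333;stroke-width:0.5}",
    " .node.sel{stroke:#000;stroke-width:3} .node.meet{stroke:#e91e63;stroke-width:3}",
    " .edge{stroke:#bbb;stroke-width:1;fill:none} #info{font-size:13px;min-height:3em}</style>",
    "</head><body>\n<h3>Hierarchical graph of pharmacophore models</h3>\n",
    "<div id=\"strip\"></div>\n<div id=\"info\">Click up to two nodes; ",
    "the intersection node of a pair is highlighted.</div>\n",
    "<svg id=\"g\" width=\"1200\" height=\"700\"></svg>\n",
    "<script>\nvar data = ", as.character(payload), ";\n",
    "var labelNodes = ", if (label_nodes) "true" else "false", ";\n",
    render_js(),
    "</script>\n</body></html>\n")
  writeLines(html, path)
  invisible(path)
}

render_js <- function() {
  # plain SVG drawing + selection logic; meet node found by bitwise AND of
  # the two selected patterns
  paste0(
"var svg = document.getElementById('g');
var W = 1200, H = 700, pad = 50;
function col(arr){return arr.length?arr:[arr];}
var nodes = col(data.nodes), edges = col(data.edges), cat = col(data.catalog);
var strip = document.getElementById('strip');
cat.forEach(function(f){
  var b = document.createElement('span');
  b.title = f.serial;
  b.style.cssText='display:inline-block;width:14px;height:14px;margin:1px;background:'+f.color+';border:1px solid #333';
  strip.appendChild(b);
});
var xs = nodes.map(function(n){return n.x}), ys = nodes.map(function(n){return n.y});
var xmin=Math.min.apply(null,xs), xmax=Math.max.apply(null,xs);
var ymin=Math.min.apply(null,ys), ymax=Math.max.apply(null,ys);
function sx(x){return xmax===xmin?W/2:pad+(x-xmin)/(xmax-xmin)*(W-2*pad);}
function sy(y){return ymax===ymin?H/2:pad+(y-ymin)/(ymax-ymin)*(H-2*pad);}
var byId = {};
nodes.forEach(function(n){byId[n.id]=n;});
edges.forEach(function(e){
  var a=byId[e.from], b=byId[e.to];
  var l=document.createElementNS('http://www.w3.org/2000/svg','line');
  l.setAttribute('class','edge');
  l.setAttribute('x1',sx(a.x)); l.setAttribute('y1',sy(a.y));
  l.setAttribute('x2',sx(b.x)); l.setAttribute('y2',sy(b.y));
  svg.appendChild(l);
});
var selected = [];
function meetPattern(p,q){
  var out='';
  for(var i=0;i<p.length;i++){out += (p[i]==='1'&&q[i]==='1')?'1':'0';}
  return out;
}
function refresh(){
  nodes.forEach(function(n){n._el.setAttribute('class','node');});
  selected.forEach(function(n){n._el.setAttribute('class','node sel');});
  if(selected.length===2){
    var mp = meetPattern(selected[0].pattern, selected[1].pattern);
    if(mp.indexOf('1')>=0){
      nodes.forEach(function(n){
        if(n.pattern===mp && selected.indexOf(n)<0){n._el.setAttribute('class','node meet');}
      });
    }
  }
}
nodes.forEach(function(n){
  var c=document.createElementNS('http://www.w3.org/2000/svg','circle');
  c.setAttribute('class','node');
  c.setAttribute('cx',sx(n.x)); c.setAttribute('cy',sy(n.y));
  c.setAttribute('r',Math.max(2,n.size/2)); c.setAttribute('fill',n.color);
  var feats=[];
  for(var i=0;i<n.pattern.length;i++){if(n.pattern[i]==='1'){feats.push(cat[i].serial);}}
  var t=document.createElementNS('http://www.w3.org/2000/svg','title');
  t.textContent=n.origin+' | count '+n.count+' | '+feats.join(', ');
  c.appendChild(t);
  c.addEventListener('click',function(){
    var i=selected.indexOf(n);
    if(i>=0){selected.splice(i,1);}else{selected.push(n); if(selected.length>2){selected.shift();}}
    document.getElementById('info').textContent =
      selected.map(function(s){return s.id+' ('+s.origin+', count '+s.count+')';}).join('  +  ');
    refresh();
  });
  n._el=c;
  svg.appendChild(c);
  if(labelNodes){
    var tx=document.createElementNS('http://www.w3.org/2000/svg','text');
    tx.setAttribute('x',sx(n.x)+6); tx.setAttribute('y',sy(n.y)-6);
    tx.setAttribute('font-size','9'); tx.textContent=n.id;
    svg.appendChild(tx);
  }
});
if(data.variance!==null){
  var v=document.createElementNS('http://www.w3.org/2000/svg','text');
  v.setAttribute('x',pad); v.setAttribute('y',20); v.setAttribute('font-size','12');
  v.textContent='variance of projection: '+Number(data.variance).toFixed(1)+'%';
  svg.appendChild(v);
}
")
}
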