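{"seed":42,"planted_modules":[["G0002","G0003","G0004","G0006","G0022","G0042"]],"true_log2fc":{"G0001":0.431691571582346,"G0002":1.83120235791042,"G0003":1.85979243049344,"G0004":1.84175093864852,"G0005":-0.205230965028047,"G0006":1.89408452381399,"G0007":-0.0513802341627003,"G0008":-0.23031156649299,"G0009":0.193123367254334,"G0010":0.198083907019677,"G0011":0.178067232983595,"G0012":-0.0639430695612241,"G0013":0.361515701907048,"G0014":-0.226260408066934,"G0015":-0.0169579187759757,"G0016":-0.0383853740963919,"G0017":-0.342304534498945,"G0018":-0.264583018578979,"G0019":0.291670430136211,"G0020":-0.277906020216464,"G0021":0.289211965408105,"G0022":2.07759483339266,"G0023":0.0577340980443923,"G0024":0.11878936068599,"G0025":0.0748890675338077,"G0026":0.136108083863292,"G0027":-0.128071993279458,"G0028":0.625358951029742,"G0029":0.102306206126144,"G0030":-0.234214635938571,"G0031":-0.203844924688341,"G0032":0.0527371630713011,"G0033":0.262943567463916,"G0034":0.171868995778647,"G0035":-0.0752725932662191,"G0036":0.124260960770245,"G0037":0.176909434884815,"G0038":0.491577942838892,"G0039":0.0211353828539945,"G0040":-0.0724415256608952,"G0041":0.122302233422615,"G0042":2.00870911634201,"G0043":-0.174591800709556,"G0044":-0.114361771727285,"G0045":-0.403997327349658,"G0046":0.414163707462436,"G0047":0.0461409362701175,"G0048":0.128851358305195,"G0049":-0.792444574068714,"G0050":0.584432860863644,"G0051":0.120071571834449,"G0052":-0.19337346512857,"G0053":-0.122810551273554,"G0054":0.0439902765864808,"G0055":-0.0645952122026611,"G0056":0.112557092813907,"G0057":0.476550592543657,"G0058":-0.0213006929003696,"G0059":-0.0312222735798725,"G0060":0.168139893069194,"G0061":0.0654096919959002,"G0062":-0.188487943396776,"G0063":0.404327204169801,"G0064":0.114638146219875,"G0065":0.0433725893530695,"G0066":0.606436010954775,"G0067":-0.160971884419183,"G0068":0.176031288374807,"G0069":0.186263934402797,"G0070":-0.123334317185305,"G0071":0.371006393028675,"G0072":0.199537836750459,"G0073":-0.0368960386311833,"G0074":0.205158738407068,"G0075":-0.00385227626071734,"G0076":-0.325773473936066,"G0077":-0.0407342293828543,"G0078":0.242755987329254,"G0079":0.0407977428479315,"G0080":-0.0215312385301431,"M001":-0.230593999176749,"M002":-0.090559384822955,"M003":-0.375504325531674,"M004":-0.0860021944160194,"M005":0.1178004594613,"M006":-0.299608927250008,"M007":-0.0375391301530226,"M008":-0.253917698081698},"module_signal_mean":2,"noise_sd":0.3}
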