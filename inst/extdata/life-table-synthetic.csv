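"sex","age","qx"
"female",30,0.000609854489610899
"female",31,0.000667287099334412
"female",32,0.000730128383939958
"female",33,0.000798887701510346
"female",34,0.000874122378560984
"female",35,0.00095644222743266
"female",36,0.00104651448910655
"female",37,0.00114506924150528
"female",38,0.00125290531711691
"female",39,0.00137089677790684
"female",40,0.0015
"female",41,0.00164126142555782
"female",42,0.00179582604468272
"female",43,0.00196494667609987
"female",44,0.00214999412184051
"female",45,0.00235246827823525
"female",46,0.00257401029327729
"female",47,0.00281641586889651
"female",48,0.00308164981596583
"female",49,0.00337186198001471
"female",50,0.00368940466673542
"female",51,0.00403685170852389
"female",52,0.00441701932659829
"female",53,0.00483298895779275
"female",54,0.00528813223104807
"female",55,0.00578613829604546
"female",56,0.00633104372549483
"female",57,0.00692726523344967
"female",58,0.0075796354748458
"female",59,0.00829344221643601
"female",60,0.00907447119661942
"female",61,0.00992905302156461
"female",62,0.0108641144777415
"female",63,0.0118872346767742
"female",64,0.0130067064876952
"female",65,0.0142316037545378
"female",66,0.0155718548440978
"female",67,0.0170383231200022
"female",68,0.0186428949953663
"female",69,0.0203985762777464
"female",70,0.0223195975873092
"female",71,0.0244215297026826
"female",72,0.0267214097694183
"female",73,0.0292378793940467
"female",74,0.0319913357430404
"female",75,0.0350040968714141
"female",76,0.0383005826210273
"female",77,0.0419075125548548
"female",78,0.0458541225315753
"female",79,0.0501724016759174
"female",80,0.054897351665517
"female",81,0.0600672704359301
"female",82,0.0657240626033609
"female",83,0.0719135791212289
"female",84,0.0786859889236486
"female",85,0.0860961855681693
"female",86,0.0942042321738025
"female",87,0.10307584826077
"female",88,0.112782942438035
"female",89,0.123404195256303
"female",90,0.135025696950783
"female",91,0.147741645242919
"female",92,0.161655108857101
"female",93,0.176878862941006
"female",94,0.193536303161067
"female",95,0.211762445882215
"female",96,0.231705022538836
"female",97,0.253525677067331
"female",98,0.277401276106025
"female",99,0.303525342582221
"female",100,0.33210962430628
"male",30,0.000853796285455258
"male",31,0.000934201939068176
"male",32,0.00102217973751594
"male",33,0.00111844278211448
"male",34,0.00122377132998538
"male",35,0.00133901911840572
"male",36,0.00146512028474917
"male",37,0.00160309693810739
"male",38,0.00175406744396367
"male",39,0.00191925548906958
"male",40,0.0021
"male",41,0.00229776599578094
"male",42,0.0025141564625558
"male",43,0.00275092534653982
"male",44,0.00300999177057671
"male",45,0.00329345558952935
"male",46,0.0036036144105882
"male",47,0.00394298221645512
"male",48,0.00431430974235216
"male",49,0.00472060677202059
"male",50,0.00516516653342959
"male",51,0.00565159239193345
"male",52,0.0061838270572376
"male",53,0.00676618454090985
"male",54,0.0074033851234673
"male",55,0.00810059361446364
"male",56,0.00886346121569276
"male",57,0.00969817132682954
"male",58,0.0106114896647841
"male",59,0.0116108191030104
"male",60,0.0127042596752672
"male",61,0.0139006742301905
"male",62,0.0152097602688381
"male",63,0.0166421285474839
"male",64,0.0182093890827733
"male",65,0.0199242452563529
"male",66,0.0218005967817369
"male",67,0.0238536523680031
"male",68,0.0261000529935128
"male",69,0.0285580067888449
"male",70,0.0312474366222329
"male",71,0.0341901415837557
"male",72,0.0374099736771856
"male",73,0.0409330311516653
"male",74,0.0447878700402565
"male",75,0.0490057356199797
"male",76,0.0536208156694382
"male",77,0.0586705175767967
"male",78,0.0641957715442054
"male",79,0.0702413623462843
"male",80,0.0768562923317238
"male",81,0.0840941786103021
"male",82,0.0920136876447053
"male",83,0.10067901076972
"male",84,0.110160384493108
"male",85,0.120534659795437
"male",86,0.131885925043323
"male",87,0.144306187565077
"male",88,0.157896119413249
"male",89,0.172765873358824
"male",90,0.189035975731096
"male",91,0.206838303340087
"male",92,0.226317152399941
"male",93,0.247630408117408
"male",94,0.270950824425494
"male",95,0.296467424235101
"male",96,0.324387031554371
"male",97,0.354935947894263
"male",98,0.388361786548435
"male",99,0.42493547961511
"male",100,0.464953474028793
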