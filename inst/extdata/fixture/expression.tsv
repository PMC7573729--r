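gene	tissue1	tissue2	tissue3	tissue4	tissue5	tissue6	tissue7	tissue8	tissue9	tissue10	tissue11	tissue12
qa_g1	1.2585064130260097	0.72231789853159167	1.2911577438038464	0.98105017156237584	2.0408103321151274	0.50800668824309969	1.1821106366661025	0.77388916377123973	1.0087959041491306	1.1452982580339035	1.6834684696789082	0.71592084414259161
qa_g5	3.5351903473984536	1.3831407220346457	2.2960030262008715	1.3432175740010901	1.7750087564601751	0.60157231113312193	0.97609288874003686	0.75016670033189548	1.2388692817054348	2.1529107627618616	2.3495876250051322	0.61675964540570738
qa_g6	4.2277040586524883	1.4277370311059581	2.1059327339347198	1.2139151798669037	 1.748455699701198	0.65030311452524681	0.98208884420155795	0.64534711307382941	0.98508616128335713	2.0429540188857347	2.5800503042750393	0.5540476386609573
qa_g2	4.1707094632196711	1.4454106379445895	1.1984606542488194	1.1334288936427801	3.1463328375301707	1.1536162578532025	2.2391535024950566	0.63990447945156326	0.6970704162979503	1.4944152473111088	2.3091947171825762	0.76805558553633235
qa_g3	2.3059086131379889	0.53155979741967263	1.2704729592925419	2.0022922390905329	1.8655565706106145	1.2793914921153164	2.3033245694793534	0.8348789312626903	0.74287916664877263	0.72327888824280928	1.2022888775106226	0.76537544401851365
qa_g4	2.5676337777749065	0.61621719334278635	1.4541936972036247	2.1069489194456783	 1.635706651651875	1.2653912145565811	2.2821361647298017	0.55995853906424853	0.36956802805133804	0.55238040381212417	0.99643596196843909	1.1797799426612328
qa_g7	0.38299550877606964	1.7909168888429003	0.79171051324205077	1.2395272779065922	0.81700355774366085	0.81014833314733026	4.2267339536164492	1.0991180923421564	0.92529745508929651	1.4184594796106296	1.4099143908459859	0.70782019912945027
qa_g8	0.37979531674968869	1.9619482726560125	0.76280560390013041	1.3098543667888682	0.71950596310713866	0.82669049205158096	4.4094799381622618	1.1998314207042973	0.85975211414014419	 1.350674018935931	1.4854008901326123	0.64506825003519697
qb_g1	0.38021129912855128	2.6978058028266982	2.5470332379333707	2.6842918228164083	0.37472481957155329	0.35873470205636671	0.39725640901931836	2.7423350193859912	0.38188362206979881	 2.791004422215507	0.37288070516258076	2.7144676020264762
qb_g2	0.36670087019123526	2.7299185296998503	0.38473292720904401	2.6878283364698081	2.5004536208354375	0.40207634934736058	2.6772617052953804	0.34016122224901968	0.38743324888092712	 2.641043389610128	2.4033052983338528	0.35445535970581421
qb_g3	0.37618581856036204	2.7215903859449586	0.36110286306134953	2.8137638398655094	2.6033859442759102	0.34427785982417125	0.35874767144937447	0.36075209203871156	2.8604172835539017	2.7927584163075205	0.36239083720715992	2.6664797005177374
qb_g7	 2.717514659983149	2.6992487844854285	2.6786488845769747	2.7074576598752174	2.6455492102268416	0.3733641741324526	2.7836366408012707	0.37501120121803744	0.35790001639784413	0.37039226546230908	0.3733617648927276	0.36686749100705229
qb_g8	2.7231098371256972	0.36812215581964042	2.6854779904126342	2.6778050654094412	0.35858042837219301	0.37748314528100385	0.36828756733790774	2.6710853802307706	0.36796705721608808	2.7292965623770336	0.36737723657437699	2.7542773748262035
qb_g4	2.7986557681984205	2.8563687788285166	0.3752478173005433	2.6757055406203523	2.7780234135297257	0.36551242789388766	0.34954727971878385	0.38416423047855031	0.34382924550501087	0.34895818396709638	2.6324027240374912	2.7086247612534651
qb_g5	2.6900405966483079	2.7103380967518631	2.7573961865477146	0.3692464676179833	0.36819787965191192	2.6420896432487408	2.7151011636993307	0.37075247939325051	0.3686184545027118	2.7589467943918584	0.36812544299580408	0.38853970411757954
qb_g6	   2.7387315200672	 2.757260728141417	0.38053718380107698	0.37187104193121429	2.6770394214510178	2.8016365277972688	 2.805214678467244	0.3602485061970192	0.35554704292405331	0.36876166304765262	 2.633315125041483	0.36634478887760735
rs_g1	0.61421906462508757	0.13593494021271052	0.31920537782332115	4.1447341102390736	0.21102134614625301	0.35649797527628391	4.9278730594551714	 2.104383710267042	0.46932525301670097	1.8065088994155487	1.9802751956565414	0.92261929027392076
rs_g5	5.7994245771204884	0.14148476387251113	0.19790772535607098	1.5653809078485474	0.12813203007853269	1.0130573794989126	6.3493600523781444	13.449546450504464	0.88927485657248762	1.6039829528914831	2.2622427528760753	7.5018135094087803
rs_g6	1.8751175893369596	0.41826534334822391	0.53680253152421076	3.2489440576278312	0.50730945960428309	0.37473205265106002	2.4508213909770813	5.4880073912658194	0.27493658272708799	3.8558991981822119	5.8714104245668022	 3.690610199124793
rs_g4	1.6915611180687933	0.4465789413673959	0.71663684685025486	4.0812413697058023	0.54311453635182594	0.49698262234973367	1.9504280633805546	4.0048814949883615	0.22891445812268196	4.7323905045855019	6.2047536369275749	3.1135556959518045
rs_g3	 1.458964681928949	0.59957695850157722	0.5454647033113188	3.6400436789423782	0.34554477139057266	0.23843271006717537	2.0044389286954276	 5.072101032319102	0.35684051103077924	3.7599258379460827	4.1361491621062623	3.3164342335067314
rs_g7	1.1912475165602658	1.4845965180752025	0.40974566563709819	1.1998036213574605	0.78165548635079296	0.65530334075737318	2.5769289687059107	1.7469834527859476	0.44630505353643191	1.0154447799866309	0.93673372607440508	0.74934613361723723
rs_g8	1.2961400765863746	1.1006346188188099	0.3892532101884994	1.3473675800709848	0.69046749213879399	0.60484345204528578	2.3637871096323622	1.5415956654572676	0.46152863135659628	1.0587241493295128	1.1316313263290416	0.72723046486661203
rs_g2	2.5796762011058676	1.7840349310894792	0.47256495153815081	 1.246115611744419	0.50792696520377256	0.70293661082290015	1.8519217777911665	2.8678286193428044	0.64898841528140305	0.51290301671158134	0.86042676413985253	0.48351219301242404
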